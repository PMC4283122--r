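#' Mine drug/side-effect relations from a whole corpus
#'
#' Runs the preprocessing pipeline and the HMM classifier on every message
#' and returns the relations extracted from messages classified positive,
#' one row per (message, side-effect term). Deterministic given the model.
#'
#' @param fit An \code{adr_hmm_fit} (or an \code{adr_hmm} with a symbol
#'   table) from \code{\link{train_hmm}}.
#' @param corpus List of \code{\link{adr_message}}.
#' @param lexset A \code{\link{lexicon_set}}.
#' @param cfg A \code{\link{pipeline_config}}.
#' @return \code{data.frame} with columns \code{message_id}, \code{drug},
#'   \code{keyword}, \code{side_effect}.
#' @export
mine_corpus <- function(fit, corpus, lexset, cfg = pipeline_config()) {
  model <- if (inherits(fit, "adr_hmm_fit")) fit$model else fit
  vocab <- model$symbol_table
  if (is.null(vocab)) stop("model must carry the training symbol table")
  rows <- lapply(corpus, function(msg) {
    obs <- run_pipeline(msg, lexset, cfg, vocab)
    res <- hmm_classify(model, obs)
    if (res$label != "positive") return(NULL)
    rel <- res$relation
    data.frame(message_id = rel$message_id, drug = rel$drug,
               keyword = rel$keyword, side_effect = rel$side_effects,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(message_id = character(0), drug = character(0),
                      keyword = character(0), side_effect = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate mined relations per drug
#'
#' For each drug: the number of messages yielding at least one relation,
#' the total number of side-effect mentions, the number of distinct
#' side-effect terms, the terms occurring strictly more than
#' \code{min_frequent} times, and each term's percentage of occurrence
#' among all side-effect mentions for the drug.
#'
#' @param relations \code{data.frame} from \code{\link{mine_corpus}}.
#' @param min_frequent Strict threshold for the frequent list (default 5,
#'   i.e. terms occurring more than 5 times).
#' @return List of \code{adr_drug_report} objects, ordered by number of
#'   messages (decreasing): each has \code{drug}, \code{n_messages},
#'   \code{total_side_effects}, \code{unique_side_effects},
#'   \code{frequent_side_effects}, and \code{percentages} (named numeric,
#'   unrounded; reports round to 2 decimals).
#' @export
aggregate_by_drug <- function(relations, min_frequent = 5) {
  if (!nrow(relations)) return(list())
  reports <- lapply(split(relations, relations$drug), function(df) {
    counts <- sort(table(df$side_effect), decreasing = TRUE)
    total <- sum(counts)
    structure(
      list(drug = df$drug[1L],
           n_messages = length(unique(df$message_id)),
           total_side_effects = as.integer(total),
           unique_side_effects = length(counts),
           frequent_side_effects = names(counts)[counts > min_frequent],
           counts = stats::setNames(as.integer(counts), names(counts)),
           percentages = stats::setNames(100 * as.numeric(counts) / total,
                                         names(counts))),
      class = "adr_drug_report"
    )
  })
  ord <- order(-vapply(reports, function(r) r$n_messages, numeric(1)),
               vapply(reports, function(r) r$drug, character(1)),
               method = "radix")
  unname(reports[ord])
}

#' @export
print.adr_drug_report <- function(x, ...) {
  cat(sprintf("<adr_drug_report %s> %d messages, %d side-effect mentions (%d unique, %d frequent)\n",
              x$drug, x$n_messages, x$total_side_effects,
              x$unique_side_effects, length(x$frequent_side_effects)))
  invisible(x)
}

#' Split a drug's mined side-effects into known and novel
#'
#' Partitions the report's side-effect terms by membership in the drug's
#' known ADR set (as published in drug package inserts). Drugs absent from
#' the table have all their side-effects treated as novel.
#'
#' @param report An \code{adr_drug_report}.
#' @param known Named list mapping drug entry to a character vector of
#'   known side-effect entries (see \code{\link{read_known_adr_table}}).
#' @return List with character vectors \code{known} and \code{novel}.
#' @export
split_known_novel <- function(report, known) {
  ses <- names(report$counts)
  ref <- known[[report$drug]]
  if (is.null(ref)) return(list(known = character(0), novel = ses))
  list(known = ses[ses %in% ref], novel = ses[!(ses %in% ref)])
}

#' Read a known-ADR reference table
#'
#' CSV with columns \code{drug} and \code{side_effect}; entries are
#' normalised like lexicon entries (casefolded, whitespace-squished).
#'
#' @param path CSV file path.
#' @return Named list: drug entry -> character vector of known
#'   side-effect entries.
#' @export
read_known_adr_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("drug", "side_effect") %in% names(df)))
  norm <- function(x) squish(stringi::stri_trans_tolower(x))
  split(norm(df$side_effect), norm(df$drug))
}

#' Tabulate drug reports for export
#'
#' One row per (drug, side-effect term) with its count, percentage (2
#' decimals) and, when a known-ADR table is supplied, a known/novel flag.
#'
#' @param reports List of \code{adr_drug_report}.
#' @param known Optional known-ADR table (see
#'   \code{\link{read_known_adr_table}}).
#' @return \code{data.frame} with columns \code{drug}, \code{side_effect},
#'   \code{count}, \code{percent}, and optionally \code{known}.
#' @export
drug_report_table <- function(reports, known = NULL) {
  rows <- lapply(reports, function(r) {
    df <- data.frame(drug = r$drug, side_effect = names(r$counts),
                     count = as.integer(r$counts),
                     percent = round_half_up(r$percentages, 2),
                     stringsAsFactors = FALSE)
    if (!is.null(known)) {
      kn <- split_known_novel(r, known)
      df$known <- df$side_effect %in% kn$known
    }
    df
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(drug = character(0), side_effect = character(0),
               count = integer(0), percent = numeric(0))
  rownames(out) <- NULL
  out
}
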