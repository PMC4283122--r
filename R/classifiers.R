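# hidden-state annotation of a processed sequence, derived from its lexicon
# matches: drug match -> Drug, side-effect match -> SideEffect, keyword
# match -> Keyword, anything else -> Other. This mirrors the two-phase
# dictionary-driven annotation used to build the training data.
derive_states <- function(obs) {
  tk <- obs$tokens
  st <- rep(.STATE_OTHER, nrow(tk))
  matched <- !is.na(tk$lexicon)
  st[matched] <- .lexicon_state[tk$lexicon[matched]]
  as.integer(st)
}

annotated_from_obs <- function(obs) {
  list(symbols = obs$tokens$symbol, states = derive_states(obs))
}

#' Classify one message with the HMM relation extractor
#'
#' Viterbi-decodes the observation sequence. The message is positive iff
#' the decoded path visits all three entity states — Drug, Keyword and
#' SideEffect — on tokens that also carry the corresponding lexicon match
#' (a token decoded as Drug without a drug-dictionary match does not
#' count). On a positive, a mined relation is built from the first decoded
#' token of each entity state; even if a drug or side-effect is mentioned
#' repeatedly, only one instance of each distinct term enters the relation.
#' An empty sequence is negative.
#'
#' @param model A trained \code{adr_hmm} (its \code{symbol_table} must be
#'   the one used to symbolize \code{obs}).
#' @param obs An \code{adr_obs} with symbols assigned.
#' @return List with \code{label} (\code{"positive"}/\code{"negative"}),
#'   \code{relation} (\code{NULL} or a list with \code{message_id},
#'   \code{drug}, \code{keyword}, \code{side_effects}), and \code{path}
#'   (decoded state indices).
#' @export
hmm_classify <- function(model, obs) {
  tk <- obs$tokens
  if (nrow(tk) == 0L)
    return(list(label = "negative", relation = NULL, path = integer(0)))
  if (any(is.na(tk$symbol)))
    stop("observation sequence has unassigned symbols; run symbolize_seq() first")
  dec <- viterbi(model, tk$symbol)
  path <- dec$path
  is_drug <- path == .STATE_DRUG & !is.na(tk$lexicon) & tk$lexicon == "drug"
  is_se <- path == .STATE_SE & !is.na(tk$lexicon) & tk$lexicon == "side_effect"
  is_kw <- path == .STATE_KW & !is.na(tk$lexicon) & tk$lexicon == "keyword"
  if (any(is_drug) && any(is_se) && any(is_kw)) {
    relation <- list(
      message_id = obs$message_id,
      drug = tk$entry[which(is_drug)[1L]],
      keyword = tk$entry[which(is_kw)[1L]],
      side_effects = unique(tk$entry[is_se])
    )
    list(label = "positive", relation = relation, path = path)
  } else {
    list(label = "negative", relation = NULL, path = path)
  }
}

#' Build the drug/side-effect co-occurrence map
#'
#' For every counted training message, each (drug, side-effect) pair of
#' dictionary entries both matched in that message increments its count by
#' exactly one, regardless of repeated mentions — a single post never
#' influences a pair's frequency more than once. By default only messages
#' gold-labelled positive are counted; \code{scope = "all"} counts every
#' training message.
#'
#' @param seqs List of preprocessed \code{adr_obs} sequences (training
#'   messages, lexicon matches computed).
#' @param labels Character vector of gold labels aligned with \code{seqs}.
#' @param scope \code{"positives"} (default) or \code{"all"}.
#' @return An object of class \code{adr_cooc} holding the pair counts.
#' @export
build_cooccurrence_map <- function(seqs, labels = NULL,
                                   scope = c("positives", "all")) {
  scope <- match.arg(scope)
  if (scope == "positives") {
    if (is.null(labels)) stop("labels are required for scope = 'positives'")
    seqs <- seqs[labels == "positive"]
  }
  keys <- unlist(lapply(seqs, function(s) message_pair_keys(s)), use.names = FALSE)
  counts <- if (length(keys)) table(keys) else integer(0)
  structure(list(counts = counts, scope = scope), class = "adr_cooc")
}

# unique (drug, side-effect) pair keys matched in one message
message_pair_keys <- function(obs) {
  tk <- obs$tokens
  drugs <- unique(tk$entry[!is.na(tk$lexicon) & tk$lexicon == "drug"])
  ses <- unique(tk$entry[!is.na(tk$lexicon) & tk$lexicon == "side_effect"])
  if (!length(drugs) || !length(ses)) return(character(0))
  as.vector(outer(drugs, ses, paste, sep = "\t"))
}

#' @export
print.adr_cooc <- function(x, ...) {
  cat(sprintf("<adr_cooc> %d drug/side-effect pairs (%s messages counted)\n",
              length(x$counts), x$scope))
  invisible(x)
}

#' Classify one message with the co-occurrence baseline
#'
#' Extracts every unique (drug, side-effect) dictionary pair matched in the
#' message and flags a pair positive iff its training co-occurrence count
#' is greater than zero; the message is positive iff at least one pair is
#' flagged. The baseline therefore cannot recognise drug/side-effect
#' combinations it has never seen in training.
#'
#' @param map An \code{adr_cooc} from \code{\link{build_cooccurrence_map}}.
#' @param obs An \code{adr_obs} (symbols not required).
#' @return List with \code{label} and \code{flagged}, a \code{data.frame}
#'   of the flagged (drug, side_effect) pairs.
#' @export
baseline_classify <- function(map, obs) {
  keys <- message_pair_keys(obs)
  hit <- keys[keys %in% names(map$counts)]
  if (length(hit)) {
    parts <- stringi::stri_split_fixed(hit, "\t", simplify = TRUE)
    flagged <- data.frame(drug = parts[, 1L], side_effect = parts[, 2L],
                          stringsAsFactors = FALSE)
    list(label = "positive", flagged = flagged)
  } else {
    list(label = "negative",
         flagged = data.frame(drug = character(0), side_effect = character(0),
                              stringsAsFactors = FALSE))
  }
}

#' Train the HMM relation extractor on a labelled corpus
#'
#' Preprocesses the corpus, builds the symbol table from the positive
#' training messages (words seen at least \code{min_count} times get their
#' own symbol), derives state annotations from the lexicon matches,
#' initialises the model from those annotated sequences, and refines it on
#' the positive sequences with Baum-Welch. The HMM is trained on positive
#' samples only; the Other state absorbs non-entity words within them.
#'
#' @param corpus List of \code{\link{adr_message}} with gold labels.
#' @param lexset A \code{\link{lexicon_set}}.
#' @param cfg A \code{\link{pipeline_config}}.
#' @param pseudocount Additive smoothing for the supervised initialization
#'   (default 0.01). It must be positive so Baum-Welch can still move
#'   probability anywhere, but small: entity states see roughly one
#'   emission per positive message, so a full Laplace count per symbol
#'   would drown those counts under the M-symbol smoothing mass and
#'   flatten the entity emissions.
#' @param tol,max_iter Baum-Welch stopping parameters. The training
#'   default \code{tol = 1e-3} (per-observation log-likelihood
#'   improvement) stops refinement at the first likelihood plateau:
#'   running EM far beyond it keeps increasing the unsupervised likelihood
#'   by reassigning the rare entity states to model background words,
#'   which destroys the state identities the relation extractor relies on.
#' @param min_count Word-symbol frequency threshold (default 2).
#' @return An object of class \code{adr_hmm_fit}: list with \code{model}
#'   (an \code{adr_hmm} carrying the symbol table) and \code{report} (the
#'   Baum-Welch training report).
#' @export
train_hmm <- function(corpus, lexset, cfg = pipeline_config(),
                      pseudocount = 0.01, tol = 1e-3, max_iter = 100L,
                      min_count = 2) {
  seqs <- preprocess_corpus(corpus, lexset, cfg)
  labels <- corpus_labels(corpus)
  fit_hmm_on_seqs(seqs, labels, lexset, pseudocount, tol, max_iter, min_count)
}

# training core shared with cross_validate (which preprocesses once)
fit_hmm_on_seqs <- function(seqs, labels, lexset, pseudocount = 0.01,
                            tol = 1e-3, max_iter = 100L, min_count = 2) {
  pos <- seqs[labels == "positive"]
  pos <- pos[vapply(pos, function(s) nrow(s$tokens) > 0L, logical(1))]
  if (!length(pos)) stop("no non-empty positive training messages")
  vocab <- build_vocab(pos, lexset, min_count = min_count)
  pos <- symbolize_corpus(pos, vocab, lexset)
  annotated <- lapply(pos, annotated_from_obs)
  model0 <- init_from_annotations(annotated, N = 4L, M = attr(vocab, "M"),
                                  pseudocount = pseudocount,
                                  state_labels = .adr_states,
                                  symbol_table = vocab)
  bw <- baum_welch(model0, lapply(pos, function(s) s$tokens$symbol),
                   tol = tol, max_iter = max_iter)
  structure(list(model = bw$model, report = bw$report), class = "adr_hmm_fit")
}

#' @export
print.adr_hmm_fit <- function(x, ...) {
  cat(sprintf("<adr_hmm_fit> M=%d symbols; Baum-Welch: %d iterations, %s\n",
              x$model$M, x$report$iterations,
              if (x$report$converged) "converged" else "not converged"))
  invisible(x)
}

#' Train the co-occurrence baseline on a labelled corpus
#'
#' @inheritParams train_hmm
#' @param scope Messages counted into the map: \code{"positives"}
#'   (default) or \code{"all"}.
#' @return An \code{adr_cooc} map.
#' @export
train_baseline <- function(corpus, lexset, cfg = pipeline_config(),
                           scope = c("positives", "all")) {
  scope <- match.arg(scope)
  seqs <- preprocess_corpus(corpus, lexset, cfg)
  build_cooccurrence_map(seqs, corpus_labels(corpus), scope = scope)
}
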