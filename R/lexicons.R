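#' Construct a lexicon from a character vector
#'
#' Entries are casefolded, whitespace-normalised, deduplicated and sorted;
#' each entry receives a stable integer id (its rank in the sorted order),
#' so the line order of a source file never affects matching.
#'
#' @param entries Character vector of single- or multi-word phrases
#'   (at most 5 tokens each).
#' @param name Lexicon name: \code{"drug"}, \code{"side_effect"} or
#'   \code{"keyword"}.
#' @return An object of class \code{adr_lexicon}.
#' @export
lexicon <- function(entries, name = c("drug", "side_effect", "keyword")) {
  name <- match.arg(name)
  entries <- stringi::stri_trans_tolower(stringi::stri_trans_nfc(entries))
  entries <- squish(entries)
  entries <- entries[nzchar(entries)]
  ntok <- lengths(stringi::stri_split_regex(entries, "\\s+", omit_empty = TRUE))
  if (any(ntok > 5L)) {
    warning(sprintf("%d entr%s longer than 5 tokens skipped in '%s' lexicon",
                    sum(ntok > 5L), if (sum(ntok > 5L) == 1) "y" else "ies", name))
    entries <- entries[ntok <= 5L]
  }
  entries <- sort(unique(entries), method = "radix")
  if (!length(entries)) stop(sprintf("lexicon '%s' has no valid entries", name))
  structure(
    list(name = name, entries = entries, ids = seq_along(entries)),
    class = "adr_lexicon"
  )
}

#' @export
print.adr_lexicon <- function(x, ...) {
  cat(sprintf("<adr_lexicon %s> %d entries\n", x$name, length(x$entries)))
  invisible(x)
}

#' Load a lexicon from a plain-text file
#'
#' One entry per line, UTF-8, \code{'#'} comments allowed, case-insensitive.
#'
#' @param path Path to the lexicon file.
#' @param name Lexicon name (see \code{\link{lexicon}}).
#' @return An \code{adr_lexicon}.
#' @export
load_lexicon <- function(path, name = c("drug", "side_effect", "keyword")) {
  name <- match.arg(name)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop(sprintf("empty lexicon file: %s", path))
  lexicon(lines, name)
}

#' The transcribed causal keyword lexicon
#'
#' The 45 keywords and phrases that signal a causal drug/side-effect
#' relationship (e.g. \code{"made me feel"}, \code{"due to"},
#' \code{"side effects"}), shipped as a package fixture.
#'
#' @return An \code{adr_lexicon} of 45 keyword entries.
#' @export
adr_keywords <- function() {
  load_lexicon(system.file("extdata", "keywords.txt", package = "adrminer"),
               "keyword")
}

#' Bundle the three entity lexicons
#'
#' @param drug,side_effect,keyword \code{adr_lexicon} objects with the
#'   matching names.
#' @param granularity Observation-symbol granularity:
#'   \code{"class_level"} (default; every drug mention emits the same
#'   symbol, which is what lets the model generalise to unseen
#'   drug/side-effect combinations) or \code{"entry_level"} (one symbol per
#'   dictionary entry).
#' @return An object of class \code{adr_lexicon_set}.
#' @export
lexicon_set <- function(drug, side_effect, keyword = adr_keywords(),
                        granularity = c("class_level", "entry_level")) {
  granularity <- match.arg(granularity)
  lexs <- list(drug = drug, side_effect = side_effect, keyword = keyword)
  for (nm in names(lexs)) {
    if (!inherits(lexs[[nm]], "adr_lexicon") || lexs[[nm]]$name != nm)
      stop(sprintf("argument '%s' must be an adr_lexicon named '%s'", nm, nm))
  }
  envs <- lapply(lexs, function(l) {
    e <- new.env(parent = emptyenv(), size = length(l$entries) * 2L)
    for (i in seq_along(l$entries)) assign(l$entries[i], l$ids[i], envir = e)
    e
  })
  max_len <- max(vapply(lexs, function(l) {
    max(lengths(stringi::stri_split_fixed(l$entries, " ")))
  }, numeric(1)))
  structure(
    list(drug = drug, side_effect = side_effect, keyword = keyword,
         granularity = granularity, envs = envs, max_len = as.integer(max_len)),
    class = "adr_lexicon_set"
  )
}

#' @export
print.adr_lexicon_set <- function(x, ...) {
  cat(sprintf("<adr_lexicon_set> drug=%d, side_effect=%d, keyword=%d (%s)\n",
              length(x$drug$entries), length(x$side_effect$entries),
              length(x$keyword$entries), x$granularity))
  invisible(x)
}

#' Match lexicon phrases in a token stream
#'
#' Greedy leftmost-longest matching, scanning left to right with a window of
#' up to 5 tokens. Matched spans never overlap. When matches of equal length
#' compete at the same start position, precedence is
#' drug > side_effect > keyword.
#'
#' @param tokens Character vector of tokens (lowercased when the plain-text
#'   filter is enabled).
#' @param lexset An \code{\link{lexicon_set}}.
#' @return A \code{data.frame} with columns \code{lexicon}, \code{entry},
#'   \code{id}, \code{start}, \code{end} (1-based inclusive token spans).
#' @export
match_phrases <- function(tokens, lexset) {
  n <- length(tokens)
  out_lex <- character(0); out_entry <- character(0)
  out_id <- integer(0); out_s <- integer(0); out_e <- integer(0)
  envs <- lexset$envs
  maxlen <- lexset$max_len
  i <- 1L
  while (i <= n) {
    hit_len <- 0L
    for (len in seq.int(min(maxlen, n - i + 1L), 1L)) {
      phrase <- paste(tokens[i:(i + len - 1L)], collapse = " ")
      for (lex in .lexicon_names) {
        id <- envs[[lex]][[phrase]]
        if (!is.null(id)) {
          out_lex <- c(out_lex, lex); out_entry <- c(out_entry, phrase)
          out_id <- c(out_id, id); out_s <- c(out_s, i)
          out_e <- c(out_e, i + len - 1L)
          hit_len <- len
          break
        }
      }
      if (hit_len > 0L) break
    }
    i <- i + max(hit_len, 1L)
  }
  data.frame(lexicon = out_lex, entry = out_entry, id = out_id,
             start = out_s, end = out_e, stringsAsFactors = FALSE)
}

#' Build the observation symbol table from training sequences
#'
#' Reserved symbols come first: the three class-level lexicon identifiers
#' and the unknown-word symbol. Unmatched words seen at least
#' \code{min_count} times in the training sequences receive their own
#' symbol; rarer words map to the unknown symbol (this bounds the symbol
#' count M and gives the unknown symbol non-zero training mass). With
#' \code{granularity = "entry_level"} every lexicon entry additionally gets
#' a dedicated symbol.
#'
#' @param seqs List of preprocessed sequences (from
#'   \code{\link{preprocess_corpus}}), normally the training fold only.
#' @param lexset An \code{\link{lexicon_set}}.
#' @param min_count Minimum training frequency for a word symbol (default 2).
#' @return Named integer vector mapping word/identifier to symbol index;
#'   attribute \code{M} gives the symbol count.
#' @export
build_vocab <- function(seqs, lexset, min_count = 2) {
  vocab <- .adr_reserved_symbols
  if (lexset$granularity == "entry_level") {
    for (lex in .lexicon_names) {
      keys <- paste0(lex, "#", lexset[[lex]]$entries)
      vocab <- c(vocab, stats::setNames(seq_along(keys) + length(vocab), keys))
    }
  }
  words <- unlist(lapply(seqs, function(s) {
    s$tokens$surface[is.na(s$tokens$lexicon)]
  }), use.names = FALSE)
  if (length(words)) {
    tab <- table(words)
    keep <- names(tab)[tab >= min_count]
    keep <- sort(keep, method = "radix")
    if (length(keep))
      vocab <- c(vocab, stats::setNames(seq_along(keep) + length(vocab), keep))
  }
  attr(vocab, "M") <- length(vocab)
  vocab
}

#' Substitute lexicon identifiers and word symbols
#'
#' Assigns an integer observation symbol to every record of a preprocessed
#' sequence: matched spans emit their class-level identifier (or per-entry
#' identifier under entry-level granularity); unmatched words emit their
#' word symbol when in the table, else the unknown symbol.
#'
#' @param seq An \code{adr_obs} from \code{\link{preprocess_corpus}}.
#' @param vocab Symbol table from \code{\link{build_vocab}} (\code{NULL}
#'   means reserved symbols only, so every word is unknown).
#' @param lexset The \code{\link{lexicon_set}} that produced the matches.
#' @return The sequence with its \code{symbol} column filled in.
#' @export
symbolize_seq <- function(seq, vocab, lexset) {
  if (is.null(vocab)) vocab <- .adr_reserved_symbols
  tk <- seq$tokens
  n <- nrow(tk)
  if (n == 0L) return(seq)
  sym <- integer(n)
  matched <- !is.na(tk$lexicon)
  if (lexset$granularity == "class_level") {
    sym[matched] <- .lexicon_symbol[tk$lexicon[matched]]
  } else if (lexset$granularity == "entry_level") {
    keys <- paste0(tk$lexicon[matched], "#", tk$entry[matched])
    v <- vocab[keys]
    v[is.na(v)] <- .SYM_UNK
    sym[matched] <- v
  } else {
    stop(sprintf("unknown lexicon granularity: '%s'", lexset$granularity))
  }
  w <- vocab[tk$surface[!matched]]
  w[is.na(w)] <- .SYM_UNK
  sym[!matched] <- w
  tk$symbol <- as.integer(sym)
  seq$tokens <- tk
  seq
}

#' @rdname symbolize_seq
#' @param seqs List of preprocessed sequences.
#' @export
symbolize_corpus <- function(seqs, vocab, lexset) {
  lapply(seqs, symbolize_seq, vocab = vocab, lexset = lexset)
}

#' Randomly subset a lexicon
#'
#' Uniform sample of \code{floor(fraction * size)} entries without
#' replacement, deterministic for a fixed seed. Used by the
#' dictionary-size ablation experiments (e.g. halving the drug dictionary).
#'
#' @param lex An \code{adr_lexicon}.
#' @param fraction Fraction of entries to keep, in (0, 1].
#' @param seed Integer seed.
#' @return A new \code{adr_lexicon} over the sampled entries.
#' @export
subset_lexicon <- function(lex, fraction, seed) {
  stopifnot(inherits(lex, "adr_lexicon"), fraction > 0, fraction <= 1)
  if (fraction == 1) return(lex)
  m <- floor(fraction * length(lex$entries))
  if (m < 1) stop("subset would be empty")
  keep <- withr::with_seed(seed, sample(lex$entries, m))
  lexicon(keep, lex$name)
}

#' Mine candidate causal keyword n-grams
#'
#' Frequency analysis of token n-grams over a corpus: returns every n-gram
#' with \code{n_min <= n <= n_max} whose corpus count is strictly greater
#' than \code{min_count}, sorted by count (descending) then
#' lexicographically. The output is a candidate list for manual curation;
#' candidates are never added to the keyword lexicon automatically.
#'
#' @param corpus_tokens List of token vectors (normalised corpus).
#' @param n_min,n_max N-gram length bounds (defaults 2 and 5).
#' @param min_count Strict lower bound on the count (default 20).
#' @return \code{data.frame} with columns \code{ngram}, \code{count}.
#' @export
mine_keyword_candidates <- function(corpus_tokens, n_min = 2, n_max = 5,
                                    min_count = 20) {
  if (n_min > n_max) stop("n_min must be <= n_max")
  grams <- character(0)
  for (toks in corpus_tokens) {
    len <- length(toks)
    for (n in seq.int(n_min, n_max)) {
      if (len < n) next
      starts <- seq_len(len - n + 1L)
      g <- toks[starts]
      if (n > 1L) {
        for (j in seq_len(n - 1L)) g <- paste(g, toks[starts + j])
      }
      grams <- c(grams, g)
    }
  }
  if (!length(grams)) {
    return(data.frame(ngram = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab <- table(grams)
  tab <- tab[tab > min_count]
  out <- data.frame(ngram = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$ngram, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
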