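#' Text-processing pipeline configuration
#'
#' The preprocessing stages mirror how forum text is normalised before
#' entity recognition: HTML stripping, plain-text normalisation (lower
#' casing, punctuation and raw-numeral removal, treated as one unit), and
#' stop-word filtering. Each stage can be toggled independently to support
#' component-removal ablation experiments.
#'
#' @param html_filter Strip HTML markup (default \code{TRUE}).
#' @param plaintext_filter Lowercase, replace punctuation with spaces and
#'   drop raw-numeral tokens (default \code{TRUE}).
#' @param stopword_filter Remove common stop words, except inside
#'   lexicon-matched phrases (default \code{TRUE}).
#' @param stopword_list_id Identifier of the stop list; \code{"english"} is
#'   the pinned list shipped with the package. Unknown identifiers are a
#'   configuration error.
#' @param stopwords Optional explicit character vector of stop words; when
#'   supplied it overrides \code{stopword_list_id}.
#' @return An object of class \code{adr_pipeline_config}.
#' @export
pipeline_config <- function(html_filter = TRUE, plaintext_filter = TRUE,
                            stopword_filter = TRUE,
                            stopword_list_id = "english",
                            stopwords = NULL) {
  if (is.null(stopwords)) {
    if (!identical(stopword_list_id, "english"))
      stop(sprintf("unknown stopword list id: '%s'", stopword_list_id))
    stopwords <- adr_stopwords()
  }
  structure(
    list(html_filter = isTRUE(html_filter),
         plaintext_filter = isTRUE(plaintext_filter),
         stopword_filter = isTRUE(stopword_filter),
         stopword_list_id = stopword_list_id,
         stopwords = stopwords),
    class = "adr_pipeline_config"
  )
}

#' The pinned English stop-word list
#'
#' @return Character vector of lowercase stop words.
#' @export
adr_stopwords <- function() {
  path <- system.file("extdata", "stopwords.txt", package = "adrminer")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  unique(lines[nzchar(lines)])
}

#' Strip HTML markup from raw text
#'
#' Best-effort extraction of the visible text: script/style content is
#' discarded, character entities are decoded, and inter-element boundaries
#' become single spaces. Malformed markup never raises an error.
#'
#' @param x Character vector of raw message texts.
#' @return Character vector of visible text.
#' @export
strip_html <- function(x) {
  vapply(x, strip_html_one, character(1), USE.NAMES = FALSE)
}

strip_html_one <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return("")
  if (!grepl("[<&]", x)) return(squish(x))
  out <- tryCatch({
    doc <- xml2::read_html(x)
    xml2::xml_remove(xml2::xml_find_all(doc, "//script|//style"))
    nodes <- xml2::xml_find_all(doc, "//text()")
    paste(xml2::xml_text(nodes), collapse = " ")
  }, error = function(e) strip_html_regex(x))
  squish(out)
}

# fallback used when libxml2 cannot parse the input at all
strip_html_regex <- function(x) {
  x <- gsub("(?is)<script\\b[^>]*>.*?</script>", " ", x, perl = TRUE)
  x <- gsub("(?is)<style\\b[^>]*>.*?</style>", " ", x, perl = TRUE)
  x <- gsub("(?s)<!--.*?-->", " ", x, perl = TRUE)
  while (grepl("<[^>]*>", x)) x <- gsub("<[^>]*>", " ", x)
  x <- decode_entities(x)
  x
}

decode_entities <- function(x) {
  named <- c("&amp;" = "&", "&lt;" = "<", "&gt;" = ">", "&quot;" = "\"",
             "&apos;" = "'", "&#39;" = "'", "&nbsp;" = " ")
  for (k in names(named)) x <- gsub(k, named[[k]], x, fixed = TRUE)
  m <- gregexpr("&#x?[0-9a-fA-F]+;", x)
  regmatches(x, m) <- lapply(regmatches(x, m), function(ents) {
    vapply(ents, function(e) {
      code <- sub("^&#x?", "", sub(";$", "", e))
      n <- if (grepl("^&#x", e)) strtoi(code, 16L) else strtoi(code, 10L)
      if (is.na(n)) e else intToUtf8(n)
    }, character(1))
  })
  x
}

squish <- function(x) {
  trimws(gsub("[[:space:]]+", " ", x))
}

#' Normalise plain text
#'
#' When the plain-text filter is enabled: NFC-normalises and casefolds the
#' text, replaces ASCII punctuation with spaces (so \code{"headache,"}
#' becomes \code{"headache"} and \code{"pain.I"} does not merge into one
#' token), drops tokens containing no letter (raw numerals such as
#' \code{"20"} or \code{"3.5"}) and strips digits from mixed tokens
#' (\code{"20mg"} to \code{"mg"}). Idempotent. With the filter disabled the
#' text is returned unchanged.
#'
#' @param x Character vector.
#' @param cfg A \code{\link{pipeline_config}}.
#' @return Character vector of normalised text.
#' @export
normalize_text <- function(x, cfg = pipeline_config()) {
  if (!cfg$plaintext_filter) return(x)
  vapply(x, normalize_text_one, character(1), USE.NAMES = FALSE)
}

normalize_text_one <- function(x) {
  if (is.na(x)) return("")
  x <- stringi::stri_trans_nfc(x)
  x <- stringi::stri_trans_tolower(x)
  x <- gsub("[[:punct:]]", " ", x, perl = TRUE)
  toks <- stringi::stri_split_regex(x, "\\s+", omit_empty = TRUE)[[1]]
  if (!length(toks)) return("")
  has_letter <- stringi::stri_detect_regex(toks, "\\p{L}")
  toks <- toks[has_letter]
  toks <- stringi::stri_replace_all_regex(toks, "\\p{Nd}", "")
  toks <- toks[nzchar(toks)]
  paste(toks, collapse = " ")
}

#' Tokenize text on whitespace
#'
#' @param x A length-1 character string.
#' @return Character vector of tokens (no empties); empty input gives an
#'   empty vector.
#' @export
tokenize_text <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  stringi::stri_split_regex(x, "\\s+", omit_empty = TRUE)[[1]]
}

#' Remove stop words outside protected spans
#'
#' Tokens inside protected spans (lexicon-matched phrases, many of which are
#' built from stop words, e.g. \code{"i am having"}) always survive.
#'
#' @param tokens Character vector of tokens.
#' @param protected Optional \code{data.frame} with \code{start}/\code{end}
#'   columns (1-based inclusive token spans) that must not be filtered.
#' @param cfg A \code{\link{pipeline_config}}; with
#'   \code{stopword_filter = FALSE} the tokens are returned unchanged.
#' @return Filtered token vector, order preserved.
#' @export
filter_stopwords <- function(tokens, protected = NULL, cfg = pipeline_config()) {
  tokens[stopword_keep_mask(tokens, protected, cfg)]
}

stopword_keep_mask <- function(tokens, protected, cfg) {
  n <- length(tokens)
  if (!cfg$stopword_filter || n == 0L) return(rep(TRUE, n))
  keep <- !(tokens %in% cfg$stopwords)
  if (!is.null(protected) && NROW(protected)) {
    for (i in seq_len(NROW(protected))) {
      s <- protected$start[i]; e <- protected$end[i]
      keep[seq.int(max(1L, s), min(n, e))] <- TRUE
    }
  }
  keep
}

#' Run the full preprocessing pipeline on one message
#'
#' Applies, in order: HTML stripping, plain-text normalisation,
#' whitespace tokenization, lexicon phrase matching, stop-word filtering
#' (protecting matched spans), and lexicon-identifier substitution. Phrase
#' matching runs before stop-word removal because many causal keyword
#' phrases are built from stop words and could otherwise never match.
#'
#' @param msg An \code{\link{adr_message}} (or a raw character string).
#' @param lexset A \code{\link{lexicon_set}}.
#' @param cfg A \code{\link{pipeline_config}}.
#' @param vocab Optional symbol table from \code{\link{build_vocab}}; when
#'   \code{NULL}, unmatched words all map to the unknown-word symbol.
#' @return An \code{adr_obs} observation sequence: a list with
#'   \code{message_id} and a \code{tokens} data frame (columns
#'   \code{surface}, \code{lexicon}, \code{entry}, \code{symbol}); matched
#'   multi-token phrases collapse to a single record.
#' @export
run_pipeline <- function(msg, lexset, cfg = pipeline_config(), vocab = NULL) {
  if (is.character(msg)) msg <- adr_message("<inline>", msg)
  seq0 <- preprocess_message(msg, lexset, cfg)
  symbolize_seq(seq0, vocab, lexset)
}

# preprocessing up to (and including) phrase matching and stop-word
# filtering, but before symbol assignment -- the symbol table is built from
# training data only, so corpus preprocessing is done once and symbolized
# per train/test split.
preprocess_message <- function(msg, lexset, cfg = pipeline_config()) {
  text <- msg$text
  if (cfg$html_filter) text <- strip_html_one(text)
  if (cfg$plaintext_filter) text <- normalize_text_one(text)
  tokens <- tokenize_text(text)
  matches <- match_phrases(tokens, lexset)
  keep <- stopword_keep_mask(tokens, matches, cfg)
  # remap match spans onto surviving token indices
  newidx <- cumsum(keep)
  tokens <- tokens[keep]
  if (nrow(matches)) {
    # matched spans always fully survive filtering, so their endpoints map
    # directly through the kept-token index
    matches$start <- newidx[matches$start]
    matches$end <- newidx[matches$end]
  }
  records <- collapse_matches(tokens, matches)
  structure(list(message_id = msg$message_id, tokens = records),
            class = "adr_obs")
}

# one record per surviving token, with matched spans collapsed to a single
# record carrying the lexicon entry
collapse_matches <- function(tokens, matches) {
  n <- length(tokens)
  if (n == 0L) {
    return(data.frame(surface = character(0), lexicon = character(0),
                      entry = character(0), symbol = integer(0),
                      stringsAsFactors = FALSE))
  }
  span_at <- integer(n)  # 0 = unmatched, else match row index
  if (nrow(matches)) {
    for (i in seq_len(nrow(matches)))
      span_at[matches$start[i]:matches$end[i]] <- i
  }
  surface <- character(0); lexicon <- character(0); entry <- character(0)
  t <- 1L
  while (t <= n) {
    m <- span_at[t]
    if (m > 0L) {
      surface <- c(surface, paste(tokens[matches$start[m]:matches$end[m]],
                                  collapse = " "))
      lexicon <- c(lexicon, matches$lexicon[m])
      entry <- c(entry, matches$entry[m])
      t <- matches$end[m] + 1L
    } else {
      surface <- c(surface, tokens[t])
      lexicon <- c(lexicon, NA_character_)
      entry <- c(entry, NA_character_)
      t <- t + 1L
    }
  }
  data.frame(surface = surface, lexicon = lexicon, entry = entry,
             symbol = NA_integer_, stringsAsFactors = FALSE)
}

#' @export
print.adr_obs <- function(x, ...) {
  cat(sprintf("<adr_obs %s> %d observations, %d entity matches\n",
              x$message_id, nrow(x$tokens), sum(!is.na(x$tokens$lexicon))))
  invisible(x)
}

# preprocess a whole corpus (no symbols yet)
#' Preprocess every message of a corpus
#'
#' Runs the pipeline stages up to lexicon matching and stop-word filtering;
#' symbols are assigned later with a training-derived symbol table (see
#' \code{\link{build_vocab}} and \code{\link{symbolize_corpus}}).
#'
#' @inheritParams run_pipeline
#' @param corpus List of \code{\link{adr_message}} objects.
#' @return List of \code{adr_obs} sequences with unassigned symbols.
#' @export
preprocess_corpus <- function(corpus, lexset, cfg = pipeline_config()) {
  lapply(corpus, preprocess_message, lexset = lexset, cfg = cfg)
}
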