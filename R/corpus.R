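#' Construct a forum message record
#'
#' A message is one forum post: raw text (possibly containing HTML), an
#' identifier, and optionally a gold ADR label with token-level entity
#' annotations.
#'
#' @param message_id Character scalar, unique message identifier.
#' @param text Raw UTF-8 message text (may be empty, never \code{NULL}).
#' @param thread_id Optional thread identifier.
#' @param label Gold message label: \code{"positive"} (contains an adverse
#'   drug reaction report), \code{"negative"}, or \code{"unknown"}.
#' @param annotation Optional \code{data.frame} with columns \code{start},
#'   \code{end} (1-based inclusive indices into the whitespace tokens of
#'   \code{text}) and \code{class} (one of \code{"drug"},
#'   \code{"side_effect"}, \code{"keyword"}). Only allowed when
#'   \code{label != "unknown"}.
#' @return An object of class \code{adr_message}.
#' @export
adr_message <- function(message_id, text, thread_id = NA_character_,
                        label = c("unknown", "positive", "negative"),
                        annotation = NULL) {
  label <- match.arg(label)
  stopifnot(is.character(message_id), length(message_id) == 1L)
  if (is.null(text) || length(text) != 1L || !is.character(text))
    stop("`text` must be a length-1 character (may be empty)")
  if (!is.null(annotation)) {
    if (label == "unknown")
      stop("gold annotation requires a gold label")
    annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
    stopifnot(all(c("start", "end", "class") %in% names(annotation)))
    if (nrow(annotation) && any(annotation$end < annotation$start))
      stop("annotation spans must have end >= start")
  }
  structure(
    list(message_id = message_id, thread_id = thread_id, text = text,
         label = label, annotation = annotation),
    class = "adr_message"
  )
}

#' @export
print.adr_message <- function(x, ...) {
  cat(sprintf("<adr_message %s> label=%s, %d chars\n",
              x$message_id, x$label, nchar(x$text)))
  invisible(x)
}

#' Read a message corpus from JSON Lines
#'
#' One JSON object per line with keys \code{message_id}, \code{thread_id},
#' \code{text}, optional \code{label}, optional \code{annotation} (a list of
#' \code{[start_token, end_token, class]} triples, 0-based, end-exclusive).
#'
#' @param path Path to a JSONL file.
#' @return A list of \code{\link{adr_message}} objects.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    ann <- NULL
    if (!is.null(rec$annotation) && length(rec$annotation)) {
      ann <- do.call(rbind, lapply(rec$annotation, function(a) {
        data.frame(start = as.integer(a[[1]]) + 1L,
                   end = as.integer(a[[2]]),  # 0-based end-exclusive -> 1-based inclusive
                   class = as.character(a[[3]]),
                   stringsAsFactors = FALSE)
      }))
    }
    adr_message(
      message_id = as.character(rec$message_id),
      text = if (is.null(rec$text)) "" else as.character(rec$text),
      thread_id = if (is.null(rec$thread_id)) NA_character_ else as.character(rec$thread_id),
      label = if (is.null(rec$label)) "unknown" else as.character(rec$label),
      annotation = ann
    )
  })
}

#' Write a message corpus as JSON Lines
#'
#' Inverse of \code{\link{read_corpus}}; writes deterministically (key order
#' fixed) so that identical corpora produce byte-identical files.
#'
#' @param corpus List of \code{\link{adr_message}} objects.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (msg in corpus) {
    rec <- list(message_id = msg$message_id)
    if (!is.na(msg$thread_id)) rec$thread_id <- msg$thread_id
    rec$text <- msg$text
    if (msg$label != "unknown") rec$label <- msg$label
    if (!is.null(msg$annotation) && nrow(msg$annotation)) {
      rec$annotation <- lapply(seq_len(nrow(msg$annotation)), function(i) {
        list(msg$annotation$start[i] - 1L,  # 1-based inclusive -> 0-based exclusive
             msg$annotation$end[i],
             msg$annotation$class[i])
      })
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con, useBytes = TRUE)
  }
  invisible(path)
}

# gold labels of a corpus as a character vector
corpus_labels <- function(corpus) {
  vapply(corpus, function(m) m$label, character(1))
}
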