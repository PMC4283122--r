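#' Synthetic corpus generator configuration
#'
#' The generator emulates the statistical structure of crawled healthcare
#' forum corpora: about a quarter of messages report an adverse drug
#' reaction; each positive contains exactly one drug mention, at least one
#' causal keyword (from the transcribed 45-phrase fixture) and one to three
#' side-effect mentions embedded among background words; negatives mix
#' empty, drug-only, side-effect-only and hard drug+side-effect-without-
#' keyword compositions; surface noise adds case variation, trailing
#' punctuation, raw numeral tokens and simple HTML markup.
#'
#' @param n_messages Number of messages (default 2000, the annotated-set
#'   scale used for cross-validation).
#' @param positive_fraction Fraction of positives (default 0.25).
#' @param mean_length Mean message length in tokens (default 40).
#' @param n_drugs,n_side_effects Sizes of the synthetic stand-in drug and
#'   side-effect lexicons (defaults 760 and 1390, mirroring the scale of
#'   the curated dictionaries; the keyword lexicon is the real fixture).
#' @param entity_start,entity_transition Entity-order model: start weights
#'   and transition weights over \{Drug, Keyword, SideEffect\}; defaults
#'   favour the cause-and-effect order Drug then Keyword then SideEffect
#'   while allowing every order.
#' @param noise List with per-token probabilities \code{html_prob},
#'   \code{uppercase_prob}, \code{punct_prob}, \code{digit_prob}.
#' @param negative_weights Composition weights for negatives over
#'   \code{none}, \code{drug_only}, \code{se_only}, \code{drug_se} (the
#'   last are hard negatives: drug and side-effect present, no keyword).
#' @param stopword_pad_prob Probability that a background padding token is
#'   a stop word rather than a pseudo-word (default 0.2).
#' @param zipf_exponent Drug and side-effect mentions are sampled with
#'   Zipf-distributed popularity (weight proportional to 1/rank^s, default
#'   s = 1): forum traffic concentrates on a few popular drugs, which is
#'   what lets a co-occurrence baseline ever see a pair twice. Set to 0
#'   for uniform sampling.
#' @param n_background Background pseudo-vocabulary size (default 2000).
#' @param seed Integer seed; identical configurations produce
#'   byte-identical corpora.
#' @return An object of class \code{adr_generator_config}.
#' @export
generator_config <- function(n_messages = 2000, positive_fraction = 0.25,
                             mean_length = 40, n_drugs = 760,
                             n_side_effects = 1390,
                             entity_start = c(Drug = 0.6, Keyword = 0.2, SideEffect = 0.2),
                             entity_transition = NULL,
                             noise = list(html_prob = 0.05, uppercase_prob = 0.1,
                                          punct_prob = 0.2, digit_prob = 0.1),
                             negative_weights = c(none = 0.4, drug_only = 0.2,
                                                  se_only = 0.2, drug_se = 0.2),
                             stopword_pad_prob = 0.2,
                             zipf_exponent = 1,
                             n_background = 2000,
                             seed = 1) {
  if (positive_fraction <= 0 || positive_fraction >= 1)
    stop("positive_fraction must be in (0, 1)")
  if (round(n_messages * positive_fraction) < 1)
    stop("positive_fraction * n_messages must be at least 1")
  if (any(negative_weights < 0) || sum(negative_weights) <= 0)
    stop("negative composition weights must be non-negative and normalizable")
  if (is.null(entity_transition)) {
    entity_transition <- rbind(
      Drug = c(Drug = 0.05, Keyword = 0.70, SideEffect = 0.25),
      Keyword = c(Drug = 0.10, Keyword = 0.05, SideEffect = 0.85),
      SideEffect = c(Drug = 0.10, Keyword = 0.30, SideEffect = 0.60)
    )
  }
  structure(
    list(n_messages = n_messages, positive_fraction = positive_fraction,
         mean_length = mean_length, n_drugs = n_drugs,
         n_side_effects = n_side_effects, entity_start = entity_start,
         entity_transition = entity_transition, noise = noise,
         negative_weights = negative_weights / sum(negative_weights),
         stopword_pad_prob = stopword_pad_prob,
         zipf_exponent = zipf_exponent,
         n_background = n_background, seed = seed),
    class = "adr_generator_config"
  )
}

# seeded pseudo-word sampler: pronounceable CV-syllable words, guaranteed
# distinct and disjoint from keyword tokens and stop words
make_pseudo_words <- function(n, suffixes = "") {
  consonants <- c("b", "c", "d", "f", "g", "k", "l", "m", "n", "p", "r",
                  "s", "t", "v", "z", "br", "cl", "dr", "pr", "st", "tr")
  vowels <- c("a", "e", "i", "o", "u", "ae", "ia", "o", "u")
  forbidden <- c(unique(unlist(strsplit(adr_keywords()$entries, " "))),
                 adr_stopwords())
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    k <- sample(2:3, need * 2L, replace = TRUE)
    words <- vapply(k, function(ns) {
      paste0(paste0(sample(consonants, ns, replace = TRUE),
                    sample(vowels, ns, replace = TRUE), collapse = ""),
             sample(suffixes, 1L))
    }, character(1))
    words <- setdiff(unique(words), c(out, forbidden))
    out <- c(out, words)
  }
  out[seq_len(n)]
}

# build the synthetic stand-in lexicons (drug/side-effect) plus background
# vocabulary, all pairwise disjoint
make_synthetic_lexicons <- function(cfg) {
  drugs <- make_pseudo_words(cfg$n_drugs,
                             suffixes = c("ol", "ine", "ide", "pril", "tan", "mab"))
  ses <- make_pseudo_words(cfg$n_side_effects,
                           suffixes = c("ache", "itis", "ness", "algia", "osis"))
  background <- make_pseudo_words(cfg$n_background, suffixes = "")
  ses <- setdiff(ses, drugs)
  background <- setdiff(background, c(drugs, ses))
  list(drug = lexicon(drugs, "drug"),
       side_effect = lexicon(ses, "side_effect"),
       background = background)
}

#' Generate a seeded synthetic annotated forum corpus
#'
#' Produces exactly \code{round(n_messages * positive_fraction)} positives
#' (deterministic assignment, then a seeded shuffle of message order).
#' Every positive embeds one drug entry, at least one keyword phrase and
#' one to three side-effect entries, ordered by the entity-order model and
#' padded with background words; negatives follow the composition weights.
#' Gold token annotations are recorded before noise and remapped across
#' inserted noise tokens. Identical configuration and seed give a
#' byte-identical corpus.
#'
#' @param cfg An \code{\link{generator_config}}.
#' @return List with \code{corpus} (list of labelled, annotated
#'   \code{\link{adr_message}}) and \code{lexicons} (the
#'   \code{\link{lexicon_set}} used, with the real keyword fixture).
#' @export
generate_corpus <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "adr_generator_config"))
  withr::with_seed(cfg$seed, generate_corpus_impl(cfg))
}

generate_corpus_impl <- function(cfg) {
  lex <- make_synthetic_lexicons(cfg)
  keywords <- adr_keywords()
  lexset <- lexicon_set(drug = lex$drug, side_effect = lex$side_effect,
                        keyword = keywords)
  n <- cfg$n_messages
  n_pos <- round(n * cfg$positive_fraction)
  labels <- c(rep("positive", n_pos), rep("negative", n - n_pos))
  labels <- labels[sample.int(n)]
  stopwords <- adr_stopwords()
  corpus <- vector("list", n)
  for (i in seq_len(n)) {
    built <- if (labels[i] == "positive") {
      build_positive_tokens(cfg, lex, keywords, stopwords)
    } else {
      build_negative_tokens(cfg, lex, keywords, stopwords)
    }
    msg <- adr_message(
      message_id = sprintf("msg%05d", i),
      text = paste(built$tokens, collapse = " "),
      thread_id = sprintf("t%04d", (i - 1L) %/% 5L + 1L),
      label = labels[i],
      annotation = built$annotation
    )
    corpus[[i]] <- inject_noise(msg, cfg$noise)
  }
  list(corpus = corpus, lexicons = lexset)
}

# sample the order in which the entity blocks appear, via the entity-order
# transition weights over {Drug, Keyword, SideEffect}
sample_entity_order <- function(items, start_w, trans_w) {
  order_out <- integer(0)
  remaining <- seq_along(items)
  classes <- .entity_class_state[vapply(items, `[[`, character(1), "class")]
  last <- NULL
  while (length(remaining)) {
    w <- if (is.null(last)) start_w[classes[remaining]] else
      trans_w[last, classes[remaining]]
    pick <- if (length(remaining) == 1L) remaining else
      sample(remaining, 1L, prob = w)
    order_out <- c(order_out, pick)
    last <- classes[pick]
    remaining <- setdiff(remaining, pick)
  }
  items[order_out]
}

# assemble a token stream from entity blocks + padding; returns tokens and
# the gold annotation spans
assemble_message <- function(entities, cfg, lex, stopwords) {
  n_entity_tokens <- sum(vapply(entities, function(e) length(e$tokens), integer(1)))
  npad <- max(0L, stats::rpois(1, cfg$mean_length) - n_entity_tokens)
  pad_pool <- function(k) {
    is_stop <- stats::runif(k) < cfg$stopword_pad_prob
    out <- character(k)
    out[is_stop] <- sample(stopwords, sum(is_stop), replace = TRUE)
    out[!is_stop] <- sample(lex$background, sum(!is_stop), replace = TRUE)
    out
  }
  # split padding into |entities|+1 gaps
  gaps <- length(entities) + 1L
  alloc <- if (npad > 0L) tabulate(sample.int(gaps, npad, replace = TRUE), gaps) else
    integer(gaps)
  tokens <- character(0)
  ann <- list()
  for (g in seq_along(entities)) {
    tokens <- c(tokens, pad_pool(alloc[g]))
    e <- entities[[g]]
    start <- length(tokens) + 1L
    tokens <- c(tokens, e$tokens)
    ann[[length(ann) + 1L]] <- data.frame(
      start = start, end = length(tokens), class = e$class,
      stringsAsFactors = FALSE)
  }
  tokens <- c(tokens, pad_pool(alloc[gaps]))
  annotation <- if (length(ann)) do.call(rbind, ann) else
    data.frame(start = integer(0), end = integer(0), class = character(0),
               stringsAsFactors = FALSE)
  list(tokens = tokens, annotation = annotation)
}

entity_block <- function(class, entry) {
  list(class = class, tokens = strsplit(entry, " ", fixed = TRUE)[[1]])
}

# Zipf popularity weights over a lexicon's entries (entry rank = id order)
zipf_weights <- function(n, s) {
  if (s == 0) rep(1, n) else 1 / seq_len(n)^s
}

build_positive_tokens <- function(cfg, lex, keywords, stopwords) {
  drug <- sample(lex$drug$entries, 1L,
                 prob = zipf_weights(length(lex$drug$entries), cfg$zipf_exponent))
  kw <- sample(keywords$entries, 1L)
  n_se <- sample(1:3, 1L)
  ses <- sample(lex$side_effect$entries, n_se,
                prob = zipf_weights(length(lex$side_effect$entries),
                                    cfg$zipf_exponent))
  entities <- c(list(entity_block("drug", drug), entity_block("keyword", kw)),
                lapply(ses, entity_block, class = "side_effect"))
  entities <- sample_entity_order(entities, cfg$entity_start,
                                  cfg$entity_transition)
  assemble_message(entities, cfg, lex, stopwords)
}

build_negative_tokens <- function(cfg, lex, keywords, stopwords) {
  kind <- sample(names(cfg$negative_weights), 1L, prob = cfg$negative_weights)
  entities <- list()
  if (kind %in% c("drug_only", "drug_se")) {
    drug <- sample(lex$drug$entries, 1L,
                   prob = zipf_weights(length(lex$drug$entries), cfg$zipf_exponent))
    entities <- c(entities, list(entity_block("drug", drug)))
  }
  if (kind %in% c("se_only", "drug_se")) {
    ses <- sample(lex$side_effect$entries, sample(1:2, 1L),
                  prob = zipf_weights(length(lex$side_effect$entries),
                                      cfg$zipf_exponent))
    entities <- c(entities, lapply(ses, entity_block, class = "side_effect"))
  }
  if (length(entities) > 1L)
    entities <- entities[sample.int(length(entities))]
  assemble_message(entities, cfg, lex, stopwords)
}

# entity-order class names used by sample_entity_order
.entity_class_state <- c(drug = "Drug", keyword = "Keyword",
                         side_effect = "SideEffect")

#' Inject surface noise into a clean message
#'
#' With the configured per-token probabilities: flips case
#' (\code{"lipitor"} to \code{"Lipitor"} or \code{"LIPITOR"}), appends
#' trailing punctuation (\code{"headache"} to \code{"headache,"}), inserts
#' digit-only tokens between tokens (outside entity spans, so gold spans
#' stay contiguous), and wraps tokens in simple HTML tags. Gold annotation
#' spans are remapped across the inserted tokens. Uses the current RNG
#' state; \code{\link{generate_corpus}} runs it under its seed.
#'
#' @param msg An \code{\link{adr_message}}.
#' @param noise List with \code{html_prob}, \code{uppercase_prob},
#'   \code{punct_prob}, \code{digit_prob} (all 0 gives the identity).
#' @return The noised \code{adr_message}.
#' @export
inject_noise <- function(msg, noise) {
  tokens <- tokenize_text(msg$text)
  n <- length(tokens)
  if (n == 0L) return(msg)
  ann <- msg$annotation
  in_span <- rep(FALSE, n)
  if (!is.null(ann) && nrow(ann)) {
    for (i in seq_len(nrow(ann)))
      in_span[ann$start[i]:ann$end[i]] <- TRUE
  }
  up <- stats::runif(n) < noise$uppercase_prob
  if (any(up)) {
    allcaps <- stats::runif(sum(up)) < 0.2
    capped <- tokens[up]
    capped[allcaps] <- toupper(capped[allcaps])
    capped[!allcaps] <- paste0(toupper(substr(capped[!allcaps], 1L, 1L)),
                               substring(capped[!allcaps], 2L))
    tokens[up] <- capped
  }
  pu <- stats::runif(n) < noise$punct_prob
  if (any(pu)) {
    tokens[pu] <- paste0(tokens[pu],
                         sample(c(",", ".", "!", "?", ";"), sum(pu),
                                replace = TRUE))
  }
  ht <- stats::runif(n) < noise$html_prob
  if (any(ht)) {
    tag <- sample(c("b", "i", "em"), sum(ht), replace = TRUE)
    tokens[ht] <- paste0("<", tag, ">", tokens[ht], "</", tag, ">")
  }
  # digit-only token insertion after positions outside entity spans
  ins_after <- which(stats::runif(n) < noise$digit_prob & !in_span)
  if (length(ins_after)) {
    digits <- as.character(sample(0:2020, length(ins_after), replace = TRUE))
    new_tokens <- character(0)
    shift <- integer(n)  # cumulative insertions at or before each position
    k <- 0L
    for (t in seq_len(n)) {
      new_tokens <- c(new_tokens, tokens[t])
      if (t %in% ins_after) {
        k <- k + 1L
        new_tokens <- c(new_tokens, digits[match(t, ins_after)])
      }
      shift[t] <- k
    }
    tokens <- new_tokens
    if (!is.null(ann) && nrow(ann)) {
      before <- c(0L, shift)[ann$start]  # insertions strictly before span start
      ann$start <- ann$start + before
      ann$end <- ann$end + before
    }
  }
  adr_message(msg$message_id, paste(tokens, collapse = " "),
              thread_id = msg$thread_id, label = msg$label, annotation = ann)
}
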