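#' Confusion counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts; their sum is the number
#'   of evaluated messages.
#' @return An object of class \code{adr_confusion}.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("confusion counts must be non-negative integers")
  structure(as.list(counts), class = "adr_confusion")
}

#' Round half away from zero
#'
#' The reporting convention for metrics: 0.5625 rounds to 0.563 at three
#' decimals (base \code{round} would give 0.562).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 3).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}

#' Precision, recall, F-score and accuracy from confusion counts
#'
#' precision = TP/(TP+FP); recall = TP/(TP+FN); F = 2PR/(P+R) computed from
#' the unrounded P and R; accuracy = (TP+TN)/total. A degenerate
#' denominator yields value 0 with its \code{defined} flag unset (which
#' keeps fold averages computable). Values are returned unrounded; reports
#' round half-up to three decimals (\code{\link{round_half_up}}).
#'
#' @param counts An \code{\link{confusion_counts}} object (or a list with
#'   elements tp, fp, tn, fn).
#' @return An object of class \code{adr_metrics}: \code{precision},
#'   \code{recall}, \code{f_score}, \code{accuracy}, and a named logical
#'   \code{defined}.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total == 0) stop("all confusion counts are zero")
  p_def <- (tp + fp) > 0
  r_def <- (tp + fn) > 0
  precision <- if (p_def) tp / (tp + fp) else 0
  recall <- if (r_def) tp / (tp + fn) else 0
  f_def <- p_def && r_def && (precision + recall) > 0
  f_score <- if (f_def) 2 * precision * recall / (precision + recall) else 0
  accuracy <- (tp + tn) / total
  structure(
    list(precision = precision, recall = recall, f_score = f_score,
         accuracy = accuracy,
         defined = c(precision = p_def, recall = r_def, f_score = f_def,
                     accuracy = TRUE)),
    class = "adr_metrics"
  )
}

#' @export
print.adr_metrics <- function(x, ...) {
  cat(sprintf("P=%.3f R=%.3f F=%.3f A=%.3f\n",
              round_half_up(x$precision), round_half_up(x$recall),
              round_half_up(x$f_score), round_half_up(x$accuracy)))
  invisible(x)
}

#' Seeded k-fold split
#'
#' Uniform seeded shuffle followed by k contiguous near-equal folds (sizes
#' differ by at most one); non-stratified. Folds are disjoint and cover the
#' corpus; the same seed always yields the same folds.
#'
#' @param n Corpus size (or a list, whose length is used).
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return List of k elements, each a list with integer index vectors
#'   \code{train} and \code{test}.
#' @export
kfold_split <- function(n, k, seed) {
  if (is.list(n)) n <- length(n)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k must not exceed the corpus size")
  perm <- withr::with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-k] + 1L)
  lapply(seq_len(k), function(i) {
    test <- perm[starts[i]:ends[i]]
    list(train = setdiff(perm, test), test = test)
  })
}

#' k-fold cross-validation of a classifier
#'
#' For each fold: the symbol table, HMM parameters (or co-occurrence map)
#' are built from the training fold only, the test fold is classified, and
#' confusion counts are accumulated against the gold labels. Preprocessing
#' and lexicon matching, which are training-independent, are computed once.
#'
#' @param corpus Labelled corpus (list of \code{\link{adr_message}}).
#' @param lexset A \code{\link{lexicon_set}}.
#' @param classifier \code{"hmm"} or \code{"baseline"}.
#' @param k Number of folds (default 10).
#' @param seed Fold-shuffle seed.
#' @param cfg A \code{\link{pipeline_config}}.
#' @param pseudocount,tol,max_iter,min_count HMM training parameters (see
#'   \code{\link{train_hmm}}).
#' @param cooc_scope Baseline map scope (see
#'   \code{\link{build_cooccurrence_map}}).
#' @return An object of class \code{adr_cv}: \code{folds} (a
#'   \code{data.frame} with per-fold counts and unrounded metrics) and
#'   \code{mean} (arithmetic mean of the per-fold metrics).
#' @export
cross_validate <- function(corpus, lexset, classifier = c("hmm", "baseline"),
                           k = 10, seed = 1, cfg = pipeline_config(),
                           pseudocount = 0.01, tol = 1e-3, max_iter = 100L,
                           min_count = 2, cooc_scope = "positives") {
  classifier <- match.arg(classifier)
  labels <- corpus_labels(corpus)
  if (any(labels == "unknown"))
    stop("cross-validation requires gold labels on every message")
  seqs <- preprocess_corpus(corpus, lexset, cfg)
  folds <- kfold_split(length(corpus), k, seed)
  rows <- lapply(seq_along(folds), function(i) {
    tr <- folds[[i]]$train; te <- folds[[i]]$test
    pred <- evaluate_fold(seqs, labels, tr, te, classifier, lexset,
                          pseudocount, tol, max_iter, min_count, cooc_scope)
    cc <- confusion_from_labels(pred, labels[te])
    m <- compute_metrics(cc)
    data.frame(fold = i, tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
               precision = m$precision, recall = m$recall,
               f_score = m$f_score, accuracy = m$accuracy)
  })
  folds_df <- do.call(rbind, rows)
  mean_metrics <- colMeans(folds_df[, c("precision", "recall", "f_score", "accuracy")])
  structure(list(folds = folds_df, mean = as.list(mean_metrics),
                 classifier = classifier, k = k, seed = seed),
            class = "adr_cv")
}

evaluate_fold <- function(seqs, labels, train_idx, test_idx, classifier,
                          lexset, pseudocount, tol, max_iter, min_count,
                          cooc_scope) {
  if (classifier == "hmm") {
    fit <- fit_hmm_on_seqs(seqs[train_idx], labels[train_idx], lexset,
                           pseudocount, tol, max_iter, min_count)
    vocab <- fit$model$symbol_table
    vapply(seqs[test_idx], function(s) {
      hmm_classify(fit$model, symbolize_seq(s, vocab, lexset))$label
    }, character(1))
  } else {
    map <- build_cooccurrence_map(seqs[train_idx], labels[train_idx],
                                  scope = cooc_scope)
    vapply(seqs[test_idx], function(s) baseline_classify(map, s)$label,
           character(1))
  }
}

confusion_from_labels <- function(pred, gold) {
  confusion_counts(
    tp = sum(pred == "positive" & gold == "positive"),
    fp = sum(pred == "positive" & gold == "negative"),
    tn = sum(pred == "negative" & gold == "negative"),
    fn = sum(pred == "negative" & gold == "positive")
  )
}

#' @export
print.adr_cv <- function(x, ...) {
  cat(sprintf("<adr_cv> %s classifier, %d folds (seed %d)\n",
              x$classifier, x$k, x$seed))
  cat(sprintf("mean: P=%.3f R=%.3f F=%.3f A=%.3f\n",
              round_half_up(x$mean$precision), round_half_up(x$mean$recall),
              round_half_up(x$mean$f_score), round_half_up(x$mean$accuracy)))
  invisible(x)
}

#' Specify an ablation variant
#'
#' @param variant Variant identifier (e.g. \code{"all_components"},
#'   \code{"no_plaintext_filter"}, \code{"drug_lexicon_halved"}).
#' @param cfg \code{\link{pipeline_config}} with the variant's stage
#'   toggles.
#' @param drug_fraction,se_fraction Fractions of the drug / side-effect
#'   lexicons retained (1 = full dictionary).
#' @param runs Number of repeated cross-validation runs (>= 1).
#' @param folds Folds per run (>= 2).
#' @param base_seed Base seed; run r uses seed \code{base_seed + r} for
#'   both the fold shuffle and the lexicon subsampling.
#' @return An object of class \code{adr_ablation_spec}.
#' @export
ablation_spec <- function(variant, cfg = pipeline_config(),
                          drug_fraction = 1, se_fraction = 1,
                          runs = 10, folds = 10, base_seed = 1) {
  stopifnot(runs >= 1, folds >= 2)
  structure(
    list(variant = variant, cfg = cfg, drug_fraction = drug_fraction,
         se_fraction = se_fraction, runs = runs, folds = folds,
         base_seed = base_seed),
    class = "adr_ablation_spec"
  )
}

#' Run component / dictionary ablation experiments
#'
#' Executes repeated cross-validation for each variant: run r uses seed
#' \code{base_seed + r} and, when the variant subsets a dictionary, the
#' same seed for the subsampling. Emits one row per (variant, run) with
#' the mean precision, recall and F-score across folds.
#'
#' @param corpus Labelled corpus.
#' @param specs List of \code{\link{ablation_spec}} objects.
#' @param lexset The full \code{\link{lexicon_set}}.
#' @param classifier \code{"hmm"} or \code{"baseline"}.
#' @param ... Passed to \code{\link{cross_validate}}.
#' @return \code{data.frame} with columns \code{variant}, \code{run},
#'   \code{mean_precision}, \code{mean_recall}, \code{mean_f}.
#' @export
run_ablation <- function(corpus, specs, lexset,
                         classifier = c("hmm", "baseline"), ...) {
  classifier <- match.arg(classifier)
  rows <- list()
  for (spec in specs) {
    for (r in seq_len(spec$runs)) {
      seed <- spec$base_seed + r
      lex <- lexset
      if (spec$drug_fraction < 1 || spec$se_fraction < 1) {
        lex <- lexicon_set(
          drug = subset_lexicon(lexset$drug, spec$drug_fraction, seed),
          side_effect = subset_lexicon(lexset$side_effect, spec$se_fraction, seed),
          keyword = lexset$keyword,
          granularity = lexset$granularity
        )
      }
      cv <- cross_validate(corpus, lex, classifier = classifier,
                           k = spec$folds, seed = seed, cfg = spec$cfg, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = spec$variant, run = r,
        mean_precision = cv$mean$precision,
        mean_recall = cv$mean$recall,
        mean_f = cv$mean$f_score,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
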