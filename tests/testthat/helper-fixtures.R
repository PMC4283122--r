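# small hand-built lexicons used across tests
tiny_lexset <- function(granularity = "class_level") {
  lexicon_set(
    drug = lexicon(c("prednisone", "lipitor", "byetta"), "drug"),
    side_effect = lexicon(c("hives", "headache", "nausea", "acid reflux"),
                          "side_effect"),
    keyword = adr_keywords(),
    granularity = granularity
  )
}

# random stochastic HMM for property tests
random_hmm <- function(N, M) {
  norm <- function(m) m / rowSums(m)
  pi <- as.vector(norm(matrix(stats::runif(N), 1)))
  A <- norm(matrix(stats::runif(N * N), N))
  B <- norm(matrix(stats::runif(N * M), N))
  hmm_model(pi, A, B)
}
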