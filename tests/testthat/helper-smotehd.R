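# In-code fixtures shared across the suite.

# small imbalanced Gaussian training set, iid N(0,1), class 2 majority
make_null_train <- function(n1 = 8, n2 = 24, p = 20, seed = 1) {
  with_seed_local(seed, {
    labeled_dataset(matrix(rnorm((n1 + n2) * p), n1 + n2, p),
                    rep(c(1L, 2L), c(n1, n2)), role = "train")
  })
}

# evaluate expr under a seed without disturbing the session RNG
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) .Random.seed else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# brute-force AUC by pair enumeration with 1/2 tie credit
brute_auc <- function(y, scores) {
  s1 <- scores[y == 1L]; s2 <- scores[y == 2L]
  tot <- 0
  for (a in s1) for (b in s2) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s2))
}

# one-sided sign test p-value that diffs are > 0 (ties dropped)
sign_test_p <- function(d, alternative = "greater") {
  d <- d[d != 0]
  if (!length(d)) return(1)
  stats::binom.test(sum(d > 0), length(d), alternative = alternative)$p.value
}
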