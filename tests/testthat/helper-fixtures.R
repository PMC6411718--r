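# Shared fixtures, built in code.

# a perfectly balanced two-clade tree with a deep split
two_clade_tree <- function(n_per_clade = 2, split = 0.9, tip = 0.1) {
  mk <- function(labels, from) {
    paste0("(", paste0(labels, ":", tip, collapse = ","), "):", split)
  }
  a <- sprintf("A%02d", seq_len(n_per_clade))
  b <- sprintf("B%02d", seq_len(n_per_clade))
  read_newick(paste0("(", mk(a), ",", mk(b), ");"))
}

# star phylogeny: identity covariance at unit depth
star_tree <- function(n = 8) {
  read_newick(paste0("(",
    paste0(sprintf("t%02d:1", seq_len(n)), collapse = ","), ");"))
}

# independent OLS oracle via explicit normal equations on the pseudoinverse
ols_oracle <- function(y, X) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * diag(solve(XtX)))
  list(beta = drop(beta), se = se)
}

# small specimen table with two species, explicit values
toy_specimens <- function() {
  data.frame(
    species = rep(c("spA", "spB"), each = 2),
    replicate = rep(c("r1", "r2"), 2),
    body_length = c(2000, 2200, 3000, 3100),
    head_width = c(700, 720, 900, 910),
    eye_width = c(1, 3, 400, 420),
    eye_height = c(2, 2, 600, 610),
    funiculus_length = c(100, 110, 240, 250),
    funiculus_width = c(40, 42, 100, 104))
}
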