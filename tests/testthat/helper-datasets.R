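# Toy-data builders used across the suite. Deliberately independent of the
# package's own synthetic generator: plain set.seed + rnorm, so oracle tests
# do not share code with the paths they check.

# iid-normal descriptor pool with a planted linear response
toy_dataset <- function(n = 20, D = 8, d_true = 2, coefs = NULL, intercept = 0,
                        noise = 0.5, n_test = 0, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * D), n, D,
              dimnames = list(sprintf("c%02d", 1:n), sprintf("x%02d", 1:D)))
  if (is.null(coefs)) coefs <- seq(2, 1, length.out = d_true)
  y <- intercept + drop(X[, seq_len(d_true), drop = FALSE] %*% coefs) +
    rnorm(n, 0, noise)
  split <- rep("train", n)
  if (n_test > 0) split[sample.int(n, n_test)] <- "test"
  acts <- data.frame(compound_id = rownames(X), pec50 = y, split = split)
  qsar_dataset(X, acts)
}

# dataset from explicit descriptor matrix and response (all training rows)
dataset_from_xy <- function(X, y) {
  if (is.null(rownames(X))) rownames(X) <- sprintf("c%02d", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%02d", seq_len(ncol(X)))
  qsar_dataset(X, data.frame(compound_id = rownames(X), pec50 = y,
                             split = "train"))
}
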