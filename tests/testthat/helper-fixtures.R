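# Shared fixtures, built in code.

# A small random network with unit scalers.
tiny_network <- function(seed = 1L, D = 8L, width = 16L) {
  freeze_network(gibbsnn_network(D = D, width = width, seed = seed))
}

# Random embedding matrix with reproducible columns.
random_embeddings <- function(n, D = 8L, seed = 1L) {
  gibbsnn:::with_seed(seed, matrix(rnorm(D * n), D, n))
}

# Random interior composition of length n.
random_simplex <- function(n) {
  x <- -log(runif(n))
  x / sum(x)
}

# In-simplex direction (components sum to zero).
simplex_direction <- function(n) {
  d <- rnorm(n)
  d - mean(d)
}

# A two-component components frame with given embeddings and flat Antoine
# coefficients (p_s = 1 bar at all T when a = b = c = 0).
pair_components <- function(E, antoine = NULL) {
  df <- data.frame(component_id = c("A", "B"), smiles = NA, name = c("A", "B"))
  emb <- as.data.frame(t(E))
  names(emb) <- paste0("emb_", seq_len(nrow(E)) - 1L)
  df <- cbind(df, emb)
  if (is.null(antoine)) antoine <- matrix(0, 2L, 3L)
  df$antoine_a <- antoine[, 1L]; df$antoine_b <- antoine[, 2L]
  df$antoine_c <- antoine[, 3L]
  df
}

# One record row of a given type (helpers around gibbsnn:::record_row).
make_record <- function(type, system_id = "S1", component_ids = "A;B", ...) {
  do.call(gibbsnn:::record_row,
          c(list(type = type, system_id = system_id,
                 component_ids = component_ids), list(...)))
}

# Independent bisection oracle for the symmetric two-suffix Margules split:
# solves ln(x/(1-x)) + A(1-2x) = 0 on (0, 1/2).
margules_gap_bisection <- function(A) {
  stopifnot(A > 2)
  f <- function(x) log(x / (1 - x)) + A * (1 - 2 * x)
  # the root lies left of the spinodal point, where f is still increasing
  lo <- 1e-12; hi <- (1 - sqrt(1 - 2 / A)) / 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  c((lo + hi) / 2, 1 - (lo + hi) / 2)
}
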