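## Gauss-Legendre nodes/weights on [-1, 1], cached per order.
.quad_cache <- new.env(parent = emptyenv())

gauss_legendre_rule <- function(n) {
  key <- paste0("gl", n)
  r <- .quad_cache[[key]]
  if (is.null(r)) {
    g <- pracma::gaussLegendre(n, -1, 1)
    r <- list(nodes = g$x, weights = g$w)
    .quad_cache[[key]] <- r
  }
  r
}

## Gauss-Hermite rule for weight exp(-t^2), order n.
gauss_hermite_rule <- function(n) {
  key <- paste0("gh", n)
  r <- .quad_cache[[key]]
  if (is.null(r)) {
    g <- pracma::gaussHermite(n)
    r <- list(nodes = g$x, weights = g$w)
    .quad_cache[[key]] <- r
  }
  r
}

## Two-dimensional tensor Gauss-Hermite grid: nodes (Q x 2), with
## log-weights already including the exp(|t|^2) adjustment used by
## adaptive quadrature: logw = log w1 + log w2 + t1^2 + t2^2.
gauss_hermite_grid <- function(n) {
  g <- gauss_hermite_rule(n)
  idx <- expand.grid(q1 = seq_len(n), q2 = seq_len(n))
  t1 <- g$nodes[idx$q1]; t2 <- g$nodes[idx$q2]
  list(nodes = cbind(t1, t2),
       logw = log(g$weights[idx$q1]) + log(g$weights[idx$q2]) +
         t1^2 + t2^2)
}

## log(sum(exp(x))) guarded against overflow; x a vector.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
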