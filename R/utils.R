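# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  expr
}

# Symmetric Dirichlet draws: n vectors of length k.
rdirichlet <- function(n, alpha, k = length(alpha)) {
  if (length(alpha) == 1) alpha <- rep(alpha, k)
  x <- matrix(stats::rgamma(n * k, shape = alpha), n, k, byrow = TRUE)
  x / rowSums(x)
}

# Jensen-Shannon divergence between two probability vectors (base-2 logs,
# bounded by 1). Used to assess source-profile separation.
#' Jensen-Shannon divergence between probability vectors
#' @param p,q probability vectors (nonnegative, positive sum).
#' @export
js_divergence <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    keep <- a > 0
    sum(a[keep] * log2(a[keep] / b[keep]))
  }
  kl(p, m) / 2 + kl(q, m) / 2
}
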