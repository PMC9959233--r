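# Internal utilities: seeding, transforms, numerics.

#' Derive a child seed from a master seed
#'
#' Counter-based derivation so that every trial / replicate draws from an
#' independent, individually re-runnable stream. Values stay below 2^31.
#'
#' @param master integer master seed.
#' @param index non-negative integer counter (trial or replicate index).
#' @param stream optional second counter separating uses within a trial.
#' @return an integer seed.
#' @export
child_seed <- function(master, index, stream = 0L) {
  master <- as.double(master)
  index <- as.double(index)
  stream <- as.double(stream)
  x <- (master %% 1000003) * 69069 + index * 40503 + stream * 6883 + 97
  as.integer(x %% 2147483629) + 1L
}

# Evaluate expr with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  # handle -Inf pairs
  out <- m + log(exp(a - m) + exp(b - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Parameter transforms between natural and unconstrained fitting scale.
# kinds: "id", "log" (positive), "logit" (0-1), "log2p" (> 2, for t df)
to_trans <- function(x, kind) {
  switch(kind,
    id = x,
    log = log(pmax(x, 1e-300)),
    logit = stats::qlogis(pmin(pmax(x, 1e-12), 1 - 1e-12)),
    log2p = log(pmax(x - 2, 1e-12)),
    stopf("unknown transform '%s'", kind)
  )
}

from_trans <- function(x, kind) {
  switch(kind,
    id = x,
    log = exp(x),
    logit = stats::plogis(x),
    log2p = 2 + exp(x),
    stopf("unknown transform '%s'", kind)
  )
}

trans_lower <- function(kind) {
  switch(kind, id = -Inf, log = log(1e-10), logit = -30, log2p = log(1e-6))
}

trans_upper <- function(kind) {
  switch(kind, id = Inf, log = log(1e8), logit = 30, log2p = log(1e8))
}

# Central-difference gradient of f at x (used for convergence diagnostics).
# Central differences cancel the curvature term, which would otherwise
# dominate for badly-scaled coordinates (e.g. covariate-by-time effects);
# the step is coarse enough that ~1e-9 relative objective noise stays small.
num_grad <- function(f, x, eps = 1e-5) {
  vapply(seq_along(x), function(k) {
    h <- eps * max(1, abs(x[k]))
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# Central-difference Hessian (small dimension only).
num_hess <- function(f, x, eps = 1e-4) {
  q <- length(x)
  H <- matrix(0, q, q)
  h <- eps * pmax(1, abs(x))
  for (k in seq_len(q)) {
    for (l in k:q) {
      if (k == l) {
        xp <- x; xp[k] <- xp[k] + h[k]
        xm <- x; xm[k] <- xm[k] - h[k]
        H[k, k] <- (f(xp) - 2 * f(x) + f(xm)) / h[k]^2
      } else {
        xpp <- x; xpp[k] <- xpp[k] + h[k]; xpp[l] <- xpp[l] + h[l]
        xpm <- x; xpm[k] <- xpm[k] + h[k]; xpm[l] <- xpm[l] - h[l]
        xmp <- x; xmp[k] <- xmp[k] - h[k]; xmp[l] <- xmp[l] + h[l]
        xmm <- x; xmm[k] <- xmm[k] - h[k]; xmm[l] <- xmm[l] - h[l]
        H[k, l] <- H[l, k] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[k] * h[l])
      }
    }
  }
  H
}
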