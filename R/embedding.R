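#' Embed representative terms in 2D semantic space
#'
#' Runs metric multidimensional scaling on the dissimilarity
#' `d(i, j) = 1 - sim(i, j)` between representatives, so that terms with
#' higher semantic similarity land closer together on the scatterplot. The
#' configuration is initialised with classical scaling ([stats::cmdscale()])
#' and polished with SMACOF majorization (Guttman transform) until the
#' normalised stress converges. The classical-scaling start is deterministic
#' and permutation-equivariant, so by default the embedding needs no
#' randomness at all; optional seeded random restarts can be requested, with
#' the lowest-stress solution kept.
#'
#' Degenerate sizes use closed forms: a single representative sits at the
#' origin; two representatives sit symmetrically on the x-axis at exactly
#' their dissimilarity apart.
#'
#' @param representatives Ordered character vector of representative term ids.
#' @param matrix Similarity matrix covering at least the representatives.
#' @param seed Integer seed, used only when `restarts > 0`; always recorded.
#' @param restarts Number of additional random starts (default 0).
#' @param max_iter,tol SMACOF iteration cap and relative stress tolerance.
#' @return A `go_embedding`: list with `coordinates` (matrix, one row per
#'   representative, columns `x`, `y`), `stress` (normalised stress-1), and
#'   `seed`.
#' @export
embed_terms <- function(representatives, matrix, seed = 42L, restarts = 0L,
                        max_iter = 300L, tol = 1e-10) {
  stopifnot(length(representatives) >= 1,
            all(representatives %in% rownames(matrix)))
  n <- length(representatives)
  d <- 1 - matrix[representatives, representatives, drop = FALSE]
  diag(d) <- 0
  d[d < 0] <- 0

  if (n == 1) {
    coords <- base::matrix(c(0, 0), 1, 2)
    stress <- 0
  } else if (n == 2) {
    h <- d[1, 2] / 2
    coords <- base::matrix(c(-h, h, 0, 0), 2, 2)
    stress <- 0
  } else {
    fit <- smacof_fit(d, init = cmdscale_init(d), max_iter = max_iter,
                      tol = tol)
    if (restarts > 0) {
      old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
      on.exit({
        if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                       envir = globalenv())
      }, add = TRUE)
      set.seed(seed)
      for (r in seq_len(restarts)) {
        init <- base::matrix(stats::rnorm(2 * n), n, 2)
        cand <- smacof_fit(d, init = init, max_iter = max_iter, tol = tol)
        if (cand$stress < fit$stress) fit <- cand
      }
    }
    coords <- fit$coords
    stress <- fit$stress
  }
  dimnames(coords) <- list(representatives, c("x", "y"))
  structure(list(coordinates = coords, stress = stress, seed = seed),
            class = "go_embedding")
}

#' @export
print.go_embedding <- function(x, ...) {
  cat("go_embedding:", nrow(x$coordinates),
      "representatives in 2D semantic space, stress",
      format(x$stress, digits = 4), "\n")
  invisible(x)
}

# classical scaling start; pads with zero columns if the double-centered
# matrix has fewer than 2 positive eigenvalues
cmdscale_init <- function(d) {
  n <- nrow(d)
  x <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = min(2L, n - 1L)))
  if (is.null(dim(x))) x <- base::matrix(x, ncol = 1)
  if (ncol(x) < 2) x <- cbind(x, base::matrix(0, n, 2 - ncol(x)))
  x
}

# SMACOF majorization with unit weights; returns centered coordinates and
# normalised stress-1 = sqrt(sum (delta - dist)^2 / sum delta^2)
smacof_fit <- function(delta, init, max_iter = 300L, tol = 1e-10) {
  n <- nrow(delta)
  x <- scale(init, center = TRUE, scale = FALSE)
  denom <- sum(delta^2) / 2
  raw_stress <- function(x) {
    dd <- as.matrix(stats::dist(x))
    sum((delta - dd)^2) / 2
  }
  s_old <- raw_stress(x)
  for (it in seq_len(max_iter)) {
    dd <- as.matrix(stats::dist(x))
    ratio <- ifelse(dd > 0, delta / dd, 0)
    b <- -ratio
    diag(b) <- 0
    diag(b) <- -rowSums(b)
    x_new <- b %*% x / n
    s_new <- raw_stress(x_new)
    if (s_old - s_new < tol * max(s_old, .Machine$double.eps)) {
      if (s_new <= s_old) x <- x_new
      break
    }
    x <- x_new
    s_old <- s_new
  }
  x <- scale(x, center = TRUE, scale = FALSE)
  stress <- if (denom > 0) sqrt(raw_stress(x) / denom) else 0
  list(coords = x[, 1:2, drop = FALSE], stress = stress)
}
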