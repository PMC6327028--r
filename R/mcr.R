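#' Estimate the chemical rank of a data matrix
#'
#' Singular value decomposition of the unmasked submatrix; the rank is the
#' number of singular values exceeding five times the noise floor, where the
#' noise floor is the median of the trailing half of the singular-value
#' spectrum.  A relative floor of `1e-10 * sv[1]` guards exactly-low-rank
#' (noiseless) matrices whose trailing singular values are numerical zeros of
#' varying magnitude.
#'
#' @param mat A [ta_matrix()] or plain numeric matrix.
#' @return Object of class `rank_estimate` with `rank` (>= 1),
#'   `singular_values` (descending), `noise_floor`.
#' @export
estimate_rank <- function(mat) {
  A <- if (inherits(mat, "ta_matrix"))
    mat$absorbance[!mat$mask, , drop = FALSE] else as.matrix(mat)
  if (nrow(A) < 2 || ncol(A) < 2)
    stop("need at least 2 unmasked wavelengths and 2 delays", call. = FALSE)
  if (all(A == 0))
    stop("degenerate all-zero matrix", call. = FALSE)
  sv <- svd(A, nu = 0, nv = 0)$d
  tail_half <- sv[(floor(length(sv) / 2) + 1):length(sv)]
  nf <- stats::median(tail_half)
  thr <- max(5 * nf, 1e-10 * sv[1])
  structure(list(rank = max(1L, sum(sv > thr)), singular_values = sv,
                 noise_floor = nf),
            class = "rank_estimate")
}

#' @export
print.rank_estimate <- function(x, ...) {
  cat(sprintf("<rank_estimate> rank %d | leading sv: %s | noise floor %.3g\n",
              x$rank, paste(sprintf("%.3g", utils::head(x$singular_values, 5)),
                            collapse = ", "), x$noise_floor))
  invisible(x)
}

#' SIMPLISMA-style purest-variable initialization
#'
#' Selects `rank` purest variables by an iterative purity criterion: the
#' first pick maximizes `mean / (sd + alpha)` (the most intense stable
#' variable, `alpha` = 5 percent of the largest variable mean as noise
#' correction); subsequent picks weight the same ratio by the determinant of
#' the correlation-around-origin matrix of the candidate with the already
#' selected variables, which drives selections toward mutual independence.
#'
#' In `"wavelength"` direction the variables are unmasked wavelength rows and
#' the selected rows (unit-maximum normalized) serve as initial
#' concentration-profile estimates.  In `"delay"` direction the variables are
#' delay columns and the selected spectra serve as initial spectral
#' estimates.  Transient-absorption matrices often have no single-species
#' wavelength (broad overlapping bands) while single-species epochs in time
#' do exist, so the delay direction is frequently the informative one.
#'
#' @param mat A [ta_matrix()].
#' @param rank Number of components.
#' @param alpha_frac Noise-correction fraction of the maximum variable mean.
#' @param direction `"wavelength"` (pure rows, initial profiles) or
#'   `"delay"` (pure columns, initial spectra).
#' @param refine In delay direction, apply the non-negativity "needle"
#'   refinement: from each selected spectrum subtract the largest multiple of
#'   every other selected spectrum that keeps it non-negative, removing the
#'   cross-contamination a mixed epoch carries (e.g. the solvated-electron
#'   background under an early-time anion spectrum).
#' @return List with `direction`, selected `wavelengths` or `delays`,
#'   `indices`, and `profiles` (rank x delays) or `spectra` (wavelengths x
#'   rank, `NA` on masked rows), normalized to unit maximum.
#' @export
initialize_purest_variables <- function(mat, rank, alpha_frac = 0.05,
                                        direction = c("wavelength", "delay"),
                                        refine = TRUE) {
  stopifnot(inherits(mat, "ta_matrix"))
  direction <- match.arg(direction)
  ok <- which(!mat$mask)
  A0 <- mat$absorbance[ok, , drop = FALSE]
  if (rank > min(dim(A0)))
    stop("rank exceeds matrix dimensions", call. = FALSE)
  A <- if (direction == "wavelength") A0 else t(A0)
  mu <- rowMeans(A)
  sdv <- apply(A, 1, stats::sd)
  alpha <- alpha_frac * max(mu)
  p <- mu / (sdv + alpha)
  lam <- sqrt(mu^2 + (sdv + alpha)^2)
  Z <- A / lam / sqrt(ncol(A))
  C <- Z %*% t(Z)                       # correlation around origin
  sel <- integer(0)
  for (k in seq_len(rank)) {
    w <- vapply(seq_len(nrow(A)), function(i) {
      if (i %in% sel) return(-Inf)
      det(C[c(i, sel), c(i, sel), drop = FALSE])
    }, numeric(1))
    score <- if (k == 1) p else p * w
    score[sel] <- -Inf
    sel <- c(sel, which.max(score))
  }
  if (direction == "wavelength") {
    prof <- A[sel, , drop = FALSE]
    prof <- prof / apply(prof, 1, max)
    list(direction = direction, wavelengths = mat$wavelengths[ok][sel],
         indices = ok[sel], profiles = prof)
  } else {
    S <- A0[, sel, drop = FALSE]
    if (refine && rank > 1) {
      for (pass in 1:2) for (i in seq_len(rank)) {
        for (j in setdiff(seq_len(rank), i)) {
          sj <- S[, j]
          big <- which(sj > 0.05 * max(sj))
          gam <- min(S[big, i] / sj[big])
          if (is.finite(gam) && gam > 0) S[, i] <- pmax(S[, i] - gam * sj, 0)
        }
      }
    }
    S <- sweep(S, 2, apply(S, 2, max), "/")
    full <- matrix(NA_real_, length(mat$wavelengths), rank)
    full[ok, ] <- S
    list(direction = direction, delays = mat$delays[sel], indices = sel,
         spectra = full)
  }
}

#' Mean spectrum over a delay window
#'
#' Average spectrum across the delays inside `t_window`, optionally
#' normalized to unit maximum; masked rows are returned as zero so the result
#' can serve as a frozen known-species column in [mcr_als()] (e.g. the
#' solvated-electron spectrum measured on the neat-solvent microsecond
#' experiment).
#'
#' @param mat A [ta_matrix()].
#' @param t_window Delay interval, ps.
#' @param normalize Scale to unit maximum?
#' @return Numeric vector over the full wavelength grid.
#' @export
mean_spectrum <- function(mat, t_window, normalize = TRUE) {
  stopifnot(inherits(mat, "ta_matrix"))
  cols <- which(mat$delays >= t_window[1] & mat$delays <= t_window[2])
  if (length(cols) == 0) stop("no delays inside `t_window`", call. = FALSE)
  s <- rowMeans(mat$absorbance[, cols, drop = FALSE])
  if (normalize) s <- s / max(s, na.rm = TRUE)
  s[mat$mask] <- 0
  s
}

# Non-negative least squares with ridge fallback on solver failure or
# rank deficiency (lambda_ridge = 1e-10 * trace of the normal matrix).
.nnls_solve <- function(C, d, nonneg = TRUE) {
  if (!nonneg) {
    x <- tryCatch(qr.solve(C, d), error = function(e) NULL)
    if (!is.null(x)) return(list(x = x, ridge = FALSE))
  } else {
    x <- tryCatch(pracma::lsqnonneg(C, d)$x, error = function(e) NULL)
    if (!is.null(x) && all(is.finite(x))) return(list(x = x, ridge = FALSE))
  }
  G <- crossprod(C)
  lam <- 1e-10 * sum(diag(G))
  x <- solve(G + lam * diag(ncol(C)), crossprod(C, d))
  if (nonneg) x <- pmax(x, 0)
  list(x = as.numeric(x), ridge = TRUE)
}

.lack_of_fit <- function(Y, S, P) {
  R <- Y - S %*% P
  100 * sqrt(sum(R^2) / sum(Y^2))
}

#' MCR-ALS species deconvolution
#'
#' Multivariate curve resolution by alternating least squares: the unmasked
#' data matrix is factorized as `Y = S P` (spectra x concentration profiles)
#' under non-negativity on both factors, solved column-by-column with
#' Lawson-Hanson non-negative least squares.  After every iteration the
#' spectra are rescaled to unit maximum (profiles compensated) to fix the
#' scale ambiguity.  Iteration stops when the lack of fit,
#' `100 * sqrt(sum(residual^2)/sum(data^2))`, changes by less than `tol`
#' percentage points, or at `max_iter`; non-convergence is flagged, not an
#' error.
#'
#' @param mat A [ta_matrix()].
#' @param rank Number of components.
#' @param init Initial profiles (rank x delays) or spectra (wavelengths x
#'   rank); default: delay-direction [initialize_purest_variables()] spectra
#'   (see its help for why the delay mode is usually the informative one).
#' @param constraints List of flags: `nonneg_spectra`, `nonneg_profiles`
#'   (default `TRUE`), `closure` (profiles columns scaled to constant sum,
#'   default `FALSE`), `unimodal_profiles` (default `FALSE`).
#' @param fixed_spectra Optional list `list(index =, spectrum =)` freezing one
#'   spectrum column (known-species variant).
#' @param max_iter Maximum ALS iterations.
#' @param tol Lack-of-fit convergence tolerance, percentage points.
#' @return Object of class `mcr_result` with `spectra` (wavelengths x rank,
#'   unit-maximum columns, `NA` on masked rows), `profiles` (rank x delays),
#'   `lack_of_fit_trace` (percent, per iteration), `iterations`, `converged`,
#'   `ridge_steps`.
#' @export
mcr_als <- function(mat, rank, init = NULL,
                    constraints = list(nonneg_spectra = TRUE,
                                       nonneg_profiles = TRUE),
                    fixed_spectra = NULL, max_iter = 500, tol = 1e-3) {
  stopifnot(inherits(mat, "ta_matrix"))
  cns <- utils::modifyList(list(nonneg_spectra = TRUE, nonneg_profiles = TRUE,
                                closure = FALSE, unimodal_profiles = FALSE),
                           constraints)
  ok <- which(!mat$mask)
  Y <- mat$absorbance[ok, , drop = FALSE]
  n_wl <- nrow(Y); n_t <- ncol(Y)
  if (is.null(init)) {
    init <- initialize_purest_variables(mat, rank,
                                        direction = "delay")$spectra
    init[is.na(init)] <- 0
  }
  init <- as.matrix(init)
  if (nrow(init) == rank && ncol(init) == n_t) {
    P <- init; S <- NULL
  } else if (nrow(init) %in% c(n_wl, length(mat$wavelengths)) &&
             ncol(init) == rank) {
    S <- if (nrow(init) == n_wl) init else init[ok, , drop = FALSE]
    P <- NULL
  } else {
    stop("`init` dimensions inconsistent with rank and the data grids",
         call. = FALSE)
  }

  ridge_steps <- 0L
  solve_factor <- function(C, Ymat, nonneg) {
    # solve C X = Ymat column-wise under optional non-negativity
    X <- matrix(0, ncol(C), ncol(Ymat))
    for (j in seq_len(ncol(Ymat))) {
      r <- .nnls_solve(C, Ymat[, j], nonneg)
      if (r$ridge) ridge_steps <<- ridge_steps + 1L
      X[, j] <- r$x
    }
    X
  }
  unimodalize <- function(v) {
    i <- which.max(v)
    if (i > 1) v[1:(i - 1)] <- rev(cummin(rev(v[1:(i - 1)])))
    if (i < length(v)) v[(i + 1):length(v)] <- cummin(v[(i + 1):length(v)])
    v
  }

  lof_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (is.null(S)) {
      # spectra step: Y' = P' S'  (rows of Y regressed on profiles)
      S <- t(solve_factor(t(P), t(Y), cns$nonneg_spectra))
    }
    if (!is.null(fixed_spectra))
      S[, fixed_spectra$index] <- fixed_spectra$spectrum[ok]
    P <- solve_factor(S, Y, cns$nonneg_profiles)
    if (cns$unimodal_profiles) P <- t(apply(P, 1, unimodalize))
    if (cns$closure) {
      cs <- colSums(P); cs[cs == 0] <- 1
      P <- sweep(P, 2, cs / stats::median(cs), "/")
    }
    # rescale spectra columns to unit maximum, compensate profiles
    m <- apply(S, 2, max); m[m <= 0] <- 1
    S <- sweep(S, 2, m, "/"); P <- sweep(P, 1, m, "*")
    lof_trace <- c(lof_trace, .lack_of_fit(Y, S, P))
    if (it > 1 && abs(lof_trace[it - 1] - lof_trace[it]) < tol) {
      converged <- TRUE
      break
    }
    S <- t(solve_factor(t(P), t(Y), cns$nonneg_spectra))
  }

  spectra <- matrix(NA_real_, length(mat$wavelengths), rank)
  spectra[ok, ] <- S
  structure(list(spectra = spectra, profiles = P,
                 lack_of_fit_trace = lof_trace, iterations = length(lof_trace),
                 converged = converged, ridge_steps = ridge_steps,
                 wavelengths = mat$wavelengths, delays = mat$delays),
            class = "mcr_result")
}

#' @export
print.mcr_result <- function(x, ...) {
  cat(sprintf(
    "<mcr_result> rank %d | %d iterations | lack of fit %.4g%% | converged: %s\n",
    ncol(x$spectra), x$iterations,
    x$lack_of_fit_trace[length(x$lack_of_fit_trace)], x$converged))
  invisible(x)
}

#' Match recovered components to reference components
#'
#' Resolves the permutation ambiguity of bilinear factorizations: finds the
#' assignment of recovered columns to reference columns maximizing the summed
#' Pearson correlation, by brute force over permutations (rank <= 6).
#'
#' @param recovered,reference Matrices with components in columns and equal
#'   column counts.
#' @return List with `permutation` (reference column j matches recovered
#'   column `permutation[j]`), `correlations` (per matched pair) and
#'   `mean_correlation`.
#' @export
match_components <- function(recovered, reference) {
  recovered <- as.matrix(recovered); reference <- as.matrix(reference)
  r <- ncol(reference)
  if (ncol(recovered) != r)
    stop("component counts differ", call. = FALSE)
  if (r > 6) stop("brute-force matching supports rank <= 6", call. = FALSE)
  keep <- stats::complete.cases(recovered) & stats::complete.cases(reference)
  cors <- stats::cor(recovered[keep, , drop = FALSE],
                     reference[keep, , drop = FALSE])
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  best <- NULL; best_score <- -Inf
  for (p in perms(seq_len(r))) {
    sc <- sum(cors[cbind(p, seq_len(r))])
    if (sc > best_score) { best_score <- sc; best <- p }
  }
  list(permutation = best,
       correlations = cors[cbind(best, seq_len(r))],
       mean_correlation = best_score / r)
}
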