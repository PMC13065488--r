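#' Penalized spline bases for the occupancy process model
#'
#' Builds the GAM representation of the occupancy linear predictor: one
#' cubic B-spline smooth with a second-difference (P-spline) penalty per
#' environmental covariate (k = 10 basis functions each) and a
#' tensor-product smooth of the planar coordinates (k = 100) capturing
#' residual spatial autocorrelation ("latitude, longitude and their
#' interaction"). Sum-to-zero constraints are absorbed into each smooth so a
#' free intercept column identifies the model. Construction and prediction
#' go through mgcv's smooth constructors, the same machinery a
#' JAGS/jagam-style Bayesian GAM uses.
#'
#' @param covariates numeric matrix of standardized covariates (named
#'   columns).
#' @param coords optional two-column matrix of planar coordinates; if
#'   supplied, the spatial tensor smooth is included.
#' @param k_cov basis dimension per covariate smooth.
#' @param k_space total basis dimension of the spatial tensor smooth.
#' @return a `spline_basis_set`: design matrix `X` (intercept first),
#'   per-smooth penalty matrices `S`, column index `blocks`, penalty ranks,
#'   and the stored smooth objects used to rebuild rows at new data.
#' @export
build_bases <- function(covariates, coords = NULL, k_cov = 10, k_space = 100) {
  covariates <- as.matrix(covariates)
  if (is.null(colnames(covariates)))
    colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
  for (j in seq_len(ncol(covariates))) {
    if (length(unique(covariates[, j])) < k_cov)
      stop_param("covariate `", colnames(covariates)[j],
                 "` has fewer unique values than basis functions (degenerate basis)")
  }
  dat <- as.data.frame(covariates)
  smooths <- list()
  for (nm in colnames(covariates)) {
    sm <- mgcv::smoothCon(
      mgcv::s(x, bs = "ps", k = k_cov), absorb.cons = TRUE,
      data = setNames(data.frame(x = dat[[nm]]), "x"))[[1]]
    sm$occufuse_var <- nm
    smooths[[nm]] <- sm
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)[, 1:2, drop = FALSE]
    km <- max(3, round(sqrt(k_space)))
    sm <- mgcv::smoothCon(
      mgcv::te(x, y, bs = "ps", k = c(km, km)), absorb.cons = TRUE,
      data = data.frame(x = coords[, 1], y = coords[, 2]))[[1]]
    sm$occufuse_var <- c("x", "y")
    smooths[["space"]] <- sm
  }

  X <- matrix(1, nrow(covariates), 1, dimnames = list(NULL, "(Intercept)"))
  blocks <- list()
  S <- list()
  ranks <- integer(0)
  for (nm in names(smooths)) {
    Xj <- smooths[[nm]]$X
    colnames(Xj) <- paste0(nm, ".", seq_len(ncol(Xj)))
    blocks[[nm]] <- ncol(X) + seq_len(ncol(Xj))
    X <- cbind(X, Xj)
    ## sum penalties for tensor smooths (two marginal penalties) into one
    ## quadratic form per smooth; symmetrize for numerical hygiene
    Sj <- Reduce(`+`, smooths[[nm]]$S)
    Sj <- (Sj + t(Sj)) / 2
    S[[nm]] <- Sj
    ranks[[nm]] <- qr(Sj)$rank
  }
  structure(list(X = X, S = S, blocks = blocks, ranks = ranks,
                 smooths = smooths, k_cov = k_cov, k_space = k_space,
                 covariate_names = colnames(covariates),
                 has_space = !is.null(coords)),
            class = "spline_basis_set")
}

#' Evaluate a basis set at new data
#'
#' Rebuilds the process-model design matrix (same columns as the stored
#' training design) at new covariate values / coordinates.
#'
#' @param bases a [build_bases()] result.
#' @param covariates matrix of standardized covariates (same columns, same
#'   standardization as at build time).
#' @param coords coordinates, required when the basis set has a spatial
#'   smooth.
#' @return design matrix with intercept column first.
#' @export
evaluate_bases <- function(bases, covariates, coords = NULL) {
  stopifnot(inherits(bases, "spline_basis_set"))
  covariates <- as.matrix(covariates)
  if (is.null(colnames(covariates)))
    colnames(covariates) <- bases$covariate_names
  n <- nrow(covariates)
  X <- matrix(1, n, 1)
  for (nm in names(bases$smooths)) {
    sm <- bases$smooths[[nm]]
    dat <- if (identical(nm, "space")) {
      if (is.null(coords)) stop_param("`coords` required: basis set has a spatial smooth")
      data.frame(x = coords[, 1], y = coords[, 2])
    } else data.frame(x = covariates[, nm])
    X <- cbind(X, mgcv::PredictMat(sm, dat))
  }
  colnames(X) <- colnames(bases$X)
  X
}

#' Linear (unpenalized) process-model design
#'
#' The linear alternative to [build_bases()]: intercept plus the
#' standardized covariates entering the occupancy logit directly. Used when
#' covariate effects are known/assumed linear (e.g. calibration experiments
#' on synthetic truth).
#'
#' @param covariates matrix of standardized covariates.
#' @return object of class `linear_design` with design `X`, no penalties.
#' @export
build_linear_design <- function(covariates) {
  covariates <- as.matrix(covariates)
  if (is.null(colnames(covariates)))
    colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
  X <- cbind("(Intercept)" = 1, covariates)
  structure(list(X = X, S = list(), blocks = list(), ranks = integer(0),
                 covariate_names = colnames(covariates), has_space = FALSE),
            class = "linear_design")
}

design_matrix_at <- function(design, covariates, coords = NULL) {
  if (inherits(design, "spline_basis_set"))
    evaluate_bases(design, covariates, coords)
  else cbind(1, as.matrix(covariates)[, design$covariate_names, drop = FALSE])
}
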