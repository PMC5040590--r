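#' Free analyte concentration in a single-site competition mixture
#'
#' Closed-form solution of the mass-action equilibrium for one analyte
#' (e.g. synGAP-alpha1) competed by one titrant species carrying a single
#' binding site (e.g. an isolated PDZ domain). Solving
#' \eqn{C^2 - C(S + P + K_D) + S P = 0} for the complex concentration C and
#' taking the physical root gives
#' \deqn{S_{free} = (S - P - K_D)/2 + \sqrt{(S + P + K_D)^2/4 - S P}}
#' where S is total analyte, P total titrant and \eqn{K_D} the dissociation
#' constant, all in nM.
#'
#' Only the plus root keeps the result inside \eqn{[0, S]}; the minus root is
#' unphysical and is never returned.
#'
#' @param analyte_total Total analyte concentration (nM), scalar or vector.
#' @param titrant_total Total titrant concentration (nM), recycled against
#'   `analyte_total`.
#' @param kd Dissociation constant (nM), `> 0`.
#' @return Free analyte concentration (nM), same length as the recycled
#'   inputs, guaranteed within `[0, analyte_total]`.
#' @examples
#' free_analyte_competition(25, 220, 220)  # ~12.855 nM
#' free_analyte_competition(25, 0, 220)    # 25: no titrant, all free
#' @export
free_analyte_competition <- function(analyte_total, titrant_total, kd) {
  stopifnot(is.numeric(analyte_total), is.numeric(titrant_total), is.numeric(kd))
  if (any(!is.finite(analyte_total)) || any(analyte_total < 0))
    stop("analyte_total must be finite and >= 0")
  if (any(!is.finite(titrant_total)) || any(titrant_total < 0))
    stop("titrant_total must be finite and >= 0")
  if (any(!is.finite(kd)) || any(kd <= 0))
    stop("kd must be finite and > 0")
  s <- analyte_total; p <- titrant_total; k <- kd
  # the free concentration is the positive root of f^2 + f(p - s + k) - ks = 0,
  # algebraically identical to the plus branch of the complex-concentration
  # quadratic; written with the rationalized small-root form to avoid
  # catastrophic cancellation when f << s (large titrant excess)
  q <- p - s + k
  disc <- q^2 + 4 * k * s
  if (any(disc < 0))
    stop("internal inconsistency: negative discriminant in free-analyte equation")
  rt <- sqrt(disc)
  free <- ifelse(q > 0, 2 * k * s / (q + rt), (rt - q) / 2)
  pmin(pmax(free, 0), s)
}

#' Hyperbolic (rectangular) binding response
#'
#' One-site saturation isotherm \eqn{R = R_{max} C / (K + C)} used for SPR
#' calibration curves, equilibrium sensorgram analysis and bead-saturation
#' intensities.
#'
#' @param rmax Maximal response (RU or AU), `> 0`.
#' @param k_half Half-saturation constant (nM), `> 0`.
#' @param conc Free concentration (nM), `>= 0`; may be a vector.
#' @return Response on the same scale as `rmax`, in `[0, rmax)`.
#' @examples
#' hyperbolic_response(100, 50, 50)  # half-saturation: 50
#' @export
hyperbolic_response <- function(rmax, k_half, conc) {
  stopifnot(rmax > 0, k_half > 0)
  if (any(conc < 0)) stop("conc must be >= 0")
  rmax * conc / (k_half + conc)
}

#' Solve a multi-ligand, multi-site-class mass-action equilibrium
#'
#' General competitive occupancy solver for linked multiple equilibria: each
#' ligand i binds each site class j independently with dissociation constant
#' `K[i, j]`, every site holds at most one ligand, and bound amounts follow
#' \deqn{bound_{ij} = T_j \frac{F_i / K_{ij}}{1 + \sum_k F_k / K_{kj}}}
#' subject to ligand conservation \eqn{F_i = L_i - \sum_j bound_{ij}}.
#'
#' The free concentrations are found by a damped fixed-point iteration on
#' \eqn{F_i = L_i / (1 + \sum_j T_j / (K_{ij} D_j))} with
#' \eqn{D_j = 1 + \sum_k F_k / K_{kj}}; because each update map is monotone
#' decreasing in the competitor free pools and the full system is a diagonally
#' dominant contraction on \eqn{[0, L]}, the fixed point is unique and the
#' solution does not depend on initialization. A Gauss-Seidel pass with
#' bracketed root-finding on each conservation equation is used as a fallback
#' when the damped iteration stalls (stiff affinity ratios).
#'
#' @param ligand_totals Named numeric vector of total ligand concentrations (nM).
#' @param site_totals Named numeric vector of total site-class concentrations (nM).
#' @param kd_matrix Numeric matrix of dissociation constants (nM), rows =
#'   ligands, columns = site classes; `Inf` or `NA` encodes "does not bind".
#' @param tol Relative convergence tolerance on conservation residuals.
#' @param max_iter Iteration cap; exceeding it is an error reporting residuals.
#' @param damping Fixed-point damping factor in (0, 1].
#' @return An object of class `equilibrium_state`: list with `free` (ligand
#'   free pools, nM), `free_sites` (unoccupied sites per class, nM), `bound`
#'   (ligand x site matrix, nM), `occupancy` (bound / site total), `residual`
#'   (max relative conservation residual) and `iterations`.
#' @examples
#' eq <- solve_multi_ligand_equilibrium(
#'   c(synGAP = 400), c(PDZ1 = 1000),
#'   matrix(220, 1, 1, dimnames = list("synGAP", "PDZ1")))
#' eq$free
#' @export
solve_multi_ligand_equilibrium <- function(ligand_totals, site_totals,
                                           kd_matrix,
                                           tol = 1e-10, max_iter = 10000L,
                                           damping = 0.5) {
  L <- as.numeric(ligand_totals); Tt <- as.numeric(site_totals)
  nl <- length(L); ns <- length(Tt)
  lig_names <- names(ligand_totals); site_names <- names(site_totals)
  if (is.null(lig_names)) lig_names <- paste0("ligand", seq_len(nl))
  if (is.null(site_names)) site_names <- paste0("site", seq_len(ns))
  K <- matrix(as.numeric(kd_matrix), nl, ns)
  K[is.na(K)] <- Inf                     # absent entry = does not bind
  if (any(L < 0) || any(Tt < 0)) stop("totals must be >= 0")
  if (any(K <= 0)) stop("all dissociation constants must be > 0 (Inf allowed)")

  if (nl == 0L) {
    bound <- matrix(numeric(0), 0, ns, dimnames = list(NULL, site_names))
    return(structure(list(free = numeric(0), free_sites = Tt, bound = bound,
                          occupancy = bound, residual = 0, iterations = 0L),
                     class = "equilibrium_state"))
  }

  A <- 1 / K                              # affinity 1/nM; 0 where no binding
  FF <- L                                 # start fully free
  it <- 0L
  residual_of <- function(FF) {
    D <- 1 + as.numeric(crossprod(A, FF))         # per-site denominators
    bound_l <- as.numeric((A %*% (Tt / D)) * FF)  # total bound per ligand
    max(abs(L - FF - bound_l) / pmax(1, L))
  }
  # per-ligand Newton solve of the conservation equation with the other
  # ligands' free pools held fixed; quadratically convergent and accurate to
  # machine precision even when the free pool is many orders of magnitude
  # below the total (stiff affinities)
  newton_one <- function(i, FF) {
    if (L[i] == 0) return(0)
    a <- A[i, ]
    cj <- 1 + as.numeric(crossprod(A, FF)) - a * FF[i]  # competitor part of D_j
    f <- max(FF[i], .Machine$double.xmin)
    for (step in seq_len(100L)) {
      den <- cj + a * f
      g <- f * (1 + sum(Tt * a / den)) - L[i]
      gp <- 1 + sum(Tt * a * cj / den^2)
      f_new <- f - g / gp
      if (f_new < 0) f_new <- f / 2
      if (f_new > L[i]) f_new <- (f + L[i]) / 2
      done <- abs(f_new - f) <= 1e-15 * max(f_new, .Machine$double.xmin)
      f <- f_new
      if (done) break
    }
    f
  }
  while (it < max_iter) {
    it <- it + 1L
    D <- 1 + as.numeric(crossprod(A, FF))
    denom <- 1 + as.numeric(A %*% (Tt / D))
    FF_new <- L / denom
    FF <- (1 - damping) * FF + damping * FF_new
    if (residual_of(FF) < tol) break
  }
  # Gauss-Seidel Newton polish (also the fallback for stiff cases where the
  # damped iteration converges slowly)
  for (sweep in seq_len(200L)) {
    for (i in seq_len(nl)) FF[i] <- newton_one(i, FF)
    if (residual_of(FF) < tol) break
  }
  D <- 1 + as.numeric(crossprod(A, FF))
  bound <- sweep(sweep(A, 1, FF, `*`), 2, Tt / D, `*`)
  dimnames(bound) <- list(lig_names, site_names)
  res <- residual_of(FF)
  if (res > tol * 10) {
    stop(sprintf(
      "equilibrium solver failed to converge after %d iterations (max relative residual %.3e)",
      it, res))
  }
  free_sites <- Tt - colSums(bound)
  occ <- sweep(bound, 2, ifelse(Tt > 0, Tt, 1), `/`)
  names(FF) <- lig_names; names(free_sites) <- site_names
  structure(list(free = FF, free_sites = free_sites, bound = bound,
                 occupancy = occ, residual = res, iterations = it),
            class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat("Mass-action equilibrium state\n")
  cat("  free ligand (nM):  ",
      paste(sprintf("%s=%.4g", names(x$free), x$free), collapse = ", "), "\n")
  cat("  free sites (nM):   ",
      paste(sprintf("%s=%.4g", names(x$free_sites), x$free_sites),
            collapse = ", "), "\n")
  cat("  bound (nM):\n")
  print(round(x$bound, 4))
  cat(sprintf("  converged in %d iterations (max residual %.2e)\n",
              x$iterations, x$residual))
  invisible(x)
}
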