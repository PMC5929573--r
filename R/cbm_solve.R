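# Flux balance analysis (LP) and minimization of metabolic adjustment (QP).
# The LP is solved by simplex after shifting fluxes by their lower bounds so
# all variables are non-negative; the QP (MOMA, and the minimum-norm
# wild-type reference) by the dual active-set method of quadprog.

ZERO_GROWTH_TOL <- 1e-6

# rows of M forming a maximal linearly independent set (QR with pivoting)
independent_rows <- function(M) {
  q <- qr(t(M))
  sort(q$pivot[seq_len(q$rank)])
}

#' Apply medium overrides to a model
#'
#' @param model A \code{metabolic_model}.
#' @param medium Named numeric vector or list: exchange reaction id ->
#'   lower flux bound (negative = uptake allowed).
#' @return The modified model.
#' @export
apply_medium <- function(model, medium) {
  if (is.null(medium) || length(medium) == 0) return(model)
  medium <- unlist(medium)
  idx <- match(names(medium), model$rxns)
  if (anyNA(idx)) {
    stopf("medium refers to unknown reaction '%s'",
          names(medium)[which(is.na(idx))[1L]])
  }
  model$lb[idx] <- as.numeric(medium)
  model
}

#' Read medium boundary conditions from a YAML file
#'
#' The file holds a \code{medium} mapping of exchange reaction ids to lower
#' flux bounds.
#'
#' @param path YAML file.
#' @return Named numeric vector.
#' @export
read_medium_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$medium)) stopf("'%s' has no 'medium' mapping", path)
  unlist(y$medium)
}

flux_solution <- function(fluxes, objective_value, status, residual = NA_real_) {
  structure(list(fluxes = fluxes, objective_value = objective_value,
                 status = status, residual = residual),
            class = "flux_solution")
}

#' Flux balance analysis
#'
#' Maximizes the biomass objective subject to steady-state mass balance
#' (S v = 0) and flux bounds.
#'
#' @param model A \code{metabolic_model}.
#' @param medium Optional medium overrides (see \code{\link{apply_medium}}).
#' @return A \code{flux_solution}: fluxes (named), objective_value, status
#'   ("optimal" or "infeasible") and the mass-balance residual.
#' @export
fba <- function(model, medium = NULL) {
  model <- apply_medium(model, medium)
  n <- length(model$rxns)
  S <- as.matrix(model$S)
  keep <- rowSums(abs(S)) > 0
  S <- S[keep, , drop = FALSE]
  cc <- as.numeric(model$rxns == model$objective)
  lb <- model$lb
  ub <- model$ub
  # shift x = v - lb so the simplex sees non-negative variables
  beq <- as.vector(-S %*% lb)
  res <- tryCatch(
    pracma::linprog(cc, A = diag(n), b = ub - lb, Aeq = S, beq = beq,
                    maximize = TRUE,
                    maxiter = max(400L, 20L * (n + nrow(S)))),
    error = function(e) NULL
  )
  if (is.null(res) || res$errno != 1 || is.null(res$x)) {
    return(flux_solution(setNames(rep(NA_real_, n), model$rxns), 0,
                         "infeasible"))
  }
  v <- res$x + lb
  resid <- max(abs(S %*% v))
  if (resid > 1e-6) {
    return(flux_solution(setNames(rep(NA_real_, n), model$rxns), 0,
                         "infeasible", resid))
  }
  flux_solution(setNames(v, model$rxns), sum(cc * v), "optimal", resid)
}

# quadratic program: min ||v - ref||^2 s.t. Aeq v = beq, lb <= v <= ub
solve_flux_qp <- function(S, ref, lb, ub, extra_eq = NULL, extra_beq = NULL) {
  n <- length(ref)
  Aeq <- rbind(S, extra_eq)
  beq <- c(rep(0, nrow(S)), extra_beq)
  keep <- independent_rows(Aeq)
  Aeq <- Aeq[keep, , drop = FALSE]
  beq <- beq[keep]
  Dmat <- diag(2, n)
  dvec <- 2 * ref
  Amat <- cbind(t(Aeq), diag(n), -diag(n))
  bvec <- c(beq, lb, -ub)
  sol <- tryCatch(
    quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = nrow(Aeq)),
    error = function(e) NULL
  )
  if (is.null(sol)) return(NULL)
  sol$solution
}

#' Reproducible wild-type reference flux distribution
#'
#' Lexicographic optimum: first maximize growth by FBA, then, holding growth
#' at its optimum, select the unique flux vector of minimum Euclidean norm.
#' This removes the arbitrariness of alternate FBA optima and makes MOMA
#' predictions deterministic.
#'
#' @param model A \code{metabolic_model}.
#' @param medium Optional medium overrides.
#' @return A \code{flux_solution}.
#' @export
fba_reference <- function(model, medium = NULL) {
  model <- apply_medium(model, medium)
  opt <- fba(model)
  if (opt$status != "optimal") return(opt)
  S <- as.matrix(model$S)
  S <- S[rowSums(abs(S)) > 0, , drop = FALSE]
  cc <- as.numeric(model$rxns == model$objective)
  v <- solve_flux_qp(S, ref = rep(0, length(cc)), lb = model$lb,
                     ub = model$ub, extra_eq = matrix(cc, nrow = 1L),
                     extra_beq = opt$objective_value)
  if (is.null(v)) return(opt)  # fall back to the plain FBA vertex
  flux_solution(setNames(v, model$rxns), sum(cc * v), "optimal",
                max(abs(S %*% v)))
}

#' Minimization of metabolic adjustment (MOMA)
#'
#' Predicts the flux state of a deletion mutant as the feasible flux vector
#' closest (in squared Euclidean distance) to a wild-type reference
#' distribution: minimize \code{sum((v - v_ref)^2)} subject to S v = 0, the
#' model bounds, and zero flux through deleted reactions. Growth is read from
#' the biomass reaction flux of the solution.
#'
#' @param model A \code{metabolic_model} (already carrying any knockout
#'   bounds, or use \code{deleted_rxns}).
#' @param reference Wild-type reference fluxes: a \code{flux_solution} or a
#'   named numeric vector; default computes \code{\link{fba_reference}} on
#'   \code{model} before deletions are applied.
#' @param deleted_rxns Reactions forced to zero flux.
#' @param linear Use the linear (L1) variant instead of the quadratic one:
#'   minimizes the sum of absolute deviations via an LP (default FALSE).
#' @return A \code{flux_solution}; an infeasible knockout reports growth 0
#'   with status "infeasible".
#' @export
moma <- function(model, reference = NULL, deleted_rxns = character(),
                 linear = FALSE) {
  if (is.null(reference)) reference <- fba_reference(model)
  ref <- if (inherits(reference, "flux_solution")) reference$fluxes
         else reference
  if (length(ref) != length(model$rxns)) {
    stopf("reference flux length %d does not match %d reactions",
          length(ref), length(model$rxns))
  }
  lb <- model$lb
  ub <- model$ub
  if (length(deleted_rxns)) {
    idx <- match(deleted_rxns, model$rxns)
    if (anyNA(idx)) {
      stopf("unknown reaction '%s'", deleted_rxns[which(is.na(idx))[1L]])
    }
    lb[idx] <- 0
    ub[idx] <- 0
  }
  S <- as.matrix(model$S)
  S <- S[rowSums(abs(S)) > 0, , drop = FALSE]
  n <- length(ref)
  if (linear) {
    # min sum |v - ref|: variables (v - lb, s) with s >= |v - ref|
    cc <- c(rep(0, n), rep(1, n))
    Aeq <- cbind(S, matrix(0, nrow(S), n))
    beq <- as.vector(-S %*% lb)
    A <- rbind(cbind(diag(n), matrix(0, n, n)),   # v - lb <= ub - lb
               cbind(diag(n), -diag(n)),          # (v-lb) - s <= ref - lb
               cbind(-diag(n), -diag(n)))         # -(v-lb) - s <= lb - ref
    b <- c(ub - lb, ref - lb, lb - ref)
    res <- tryCatch(
      pracma::linprog(cc, A = A, b = b, Aeq = Aeq, beq = beq,
                      maximize = FALSE,
                      maxiter = max(800L, 40L * (2L * n + nrow(S)))),
      error = function(e) NULL
    )
    if (is.null(res) || res$errno != 1 || is.null(res$x)) {
      return(flux_solution(setNames(rep(NA_real_, n), model$rxns), 0,
                           "infeasible"))
    }
    v <- res$x[seq_len(n)] + lb
  } else {
    v <- solve_flux_qp(S, ref = unname(ref), lb = lb, ub = ub)
    if (is.null(v)) {
      return(flux_solution(setNames(rep(NA_real_, n), model$rxns), 0,
                           "infeasible"))
    }
  }
  resid <- max(abs(S %*% v))
  growth <- v[match(model$objective, model$rxns)]
  flux_solution(setNames(v, model$rxns), growth, "optimal", resid)
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("flux_solution: status %s, objective %.6g\n",
              x$status, x$objective_value))
  invisible(x)
}
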