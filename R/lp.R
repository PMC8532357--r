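#' Solve a linear program over the flux polytope
#'
#' Optimizes a linear objective over \eqn{\{v : Sv = 0, lb \le v \le ub\}}
#' with a bounded-variable two-phase primal simplex (Bland's rule, so
#' termination is guaranteed under degeneracy). All bounds must be finite,
#' which constraint-based models guarantee by convention (defaults
#' \eqn{\pm 1000}); with finite bounds the LP is never unbounded.
#'
#' @param system A `stoichiometric_system` from
#'   [build_stoichiometric_system()].
#' @param objective Numeric objective vector, length `n_reactions`, or a
#'   single reaction id (objective = that unit flux).
#' @param sense `"max"` or `"min"`.
#' @param tol Feasibility/optimality tolerance.
#' @return A list with `status` (`"optimal"` or `"infeasible"`),
#'   `objective` (optimal value, `NA` if infeasible) and `flux` (named
#'   optimal flux vector, `NULL` if infeasible).
#' @export
solve_lp <- function(system, objective, sense = c("max", "min"),
                     tol = 1e-9) {
  sense <- match.arg(sense)
  stopifnot(inherits(system, "stoichiometric_system"))
  n <- length(system$reaction_ids)
  if (is.character(objective) && length(objective) == 1) {
    j <- match(objective, system$reaction_ids)
    if (is.na(j)) stop("unknown reaction id in objective: ", objective)
    objective <- replace(numeric(n), j, 1)
  }
  stopifnot(length(objective) == n)
  if (any(!is.finite(system$lb)) || any(!is.finite(system$ub))) {
    stop("solve_lp requires finite bounds on every reaction")
  }
  cc <- if (sense == "max") -objective else objective
  res <- simplex_bounded(system$S, rep(0, nrow(system$S)),
                         unname(system$lb), unname(system$ub), cc, tol)
  if (res$status != "optimal") {
    return(list(status = res$status, objective = NA_real_, flux = NULL))
  }
  v <- stats::setNames(res$x, system$reaction_ids)
  list(status = "optimal", objective = sum(objective * v), flux = v)
}

# Bounded-variable two-phase primal simplex for
#   min c'x  s.t.  A x = b,  lb <= x <= ub   (all bounds finite).
# Artificial variables cover rank-deficient rows (they may remain basic at
# zero). Bland's smallest-index rule prevents cycling.
simplex_bounded <- function(A, b, lb, ub, cc, tol = 1e-9,
                            max_iter = 20000L) {
  m <- nrow(A); n <- ncol(A)
  scale <- max(1, max(abs(c(lb, ub))))

  # initial nonbasic values: the bound of smaller magnitude
  at_upper <- abs(ub) < abs(lb)
  x <- ifelse(at_upper, ub, lb)
  r <- b - as.vector(A %*% x)
  s <- ifelse(r >= 0, 1, -1)
  Aext <- cbind(A, diag(s, nrow = m))
  lbe <- c(lb, rep(0, m))
  ube <- c(ub, rep(Inf, m))
  xe <- c(x, abs(r))
  at_upper <- c(at_upper, rep(FALSE, m))
  basis <- n + seq_len(m)

  run_phase <- function(cost, xe, at_upper, basis, ube) {
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) stop("simplex iteration limit exceeded")
      Bmat <- Aext[, basis, drop = FALSE]
      nonbasic <- setdiff(seq_len(n + m), basis)
      # refresh basic values from the nonbasic ones (drift control)
      rhs <- b - as.vector(Aext[, nonbasic, drop = FALSE] %*% xe[nonbasic])
      xB <- tryCatch(solve(Bmat, rhs), error = function(e) {
        stop("singular basis in simplex (numerical failure)")
      })
      xe[basis] <- xB
      y <- solve(t(Bmat), cost[basis])
      d <- cost[nonbasic] - as.vector(crossprod(Aext[, nonbasic, drop = FALSE], y))
      elig <- (!at_upper[nonbasic] & d < -tol) |
              (at_upper[nonbasic] & d > tol)
      if (!any(elig)) {
        return(list(xe = xe, at_upper = at_upper, basis = basis,
                    value = sum(cost * xe)))
      }
      q <- min(nonbasic[elig])            # Bland: smallest entering index
      dir <- if (at_upper[q]) -1 else 1
      w <- solve(Bmat, Aext[, q])
      delta <- -dir * w                   # change of basic vars per unit t
      t_flip <- ube[q] - lbe[q]           # entering reaches opposite bound
      t_best <- t_flip; leave_pos <- 0L
      for (i in seq_len(m)) {
        if (delta[i] > tol) {
          ti <- (ube[basis[i]] - xe[basis[i]]) / delta[i]
        } else if (delta[i] < -tol) {
          ti <- (xe[basis[i]] - lbe[basis[i]]) / (-delta[i])
        } else next
        ti <- max(ti, 0)
        if (ti < t_best - tol * scale ||
            (ti < t_best + tol * scale && leave_pos > 0L &&
             basis[i] < basis[leave_pos])) {
          t_best <- ti; leave_pos <- i
        }
      }
      if (!is.finite(t_best)) stop("unbounded LP despite finite bounds")
      # apply the step
      xe[q] <- xe[q] + dir * t_best
      xe[basis] <- xe[basis] + delta * t_best
      if (leave_pos == 0L) {
        at_upper[q] <- !at_upper[q]       # bound flip, basis unchanged
        xe[q] <- if (at_upper[q]) ube[q] else lbe[q]
      } else {
        p <- basis[leave_pos]
        hit_upper <- delta[leave_pos] > 0
        xe[p] <- if (hit_upper) ube[p] else lbe[p]
        at_upper[p] <- hit_upper
        basis[leave_pos] <- q
      }
    }
  }

  # phase 1: drive artificials to zero
  cost1 <- c(rep(0, n), rep(1, m))
  ph1 <- run_phase(cost1, xe, at_upper, basis, ube)
  if (ph1$value > 1e-7 * scale) {
    return(list(status = "infeasible", x = NULL))
  }
  # phase 2: artificials frozen at zero via ub = 0
  ube2 <- c(ub, rep(0, m))
  xe2 <- ph1$xe
  xe2[n + seq_len(m)][abs(xe2[n + seq_len(m)]) < 1e-9 * scale] <- 0
  cost2 <- c(cc, rep(0, m))
  ph2 <- run_phase(cost2, xe2, ph1$at_upper, ph1$basis, ube2)
  x <- ph2$xe[seq_len(n)]
  x <- pmin(pmax(x, lb), ub)              # clamp roundoff at the bounds
  list(status = "optimal", x = x, value = sum(cc * x))
}

#' Flux variability analysis
#'
#' Computes the LP minimum and maximum of every reaction flux over the
#' constrained polytope. Errors before any per-reaction solve when the
#' system is infeasible.
#'
#' @param system A `stoichiometric_system`.
#' @param tol LP tolerance.
#' @return A tibble with columns `reaction_id`, `min`, `max`.
#' @export
flux_variability <- function(system, tol = 1e-9) {
  stopifnot(inherits(system, "stoichiometric_system"))
  feas <- solve_lp(system, rep(0, length(system$reaction_ids)), "min", tol)
  if (feas$status != "optimal") {
    stop("system is infeasible; flux variability is undefined")
  }
  n <- length(system$reaction_ids)
  res <- purrr::map_dfr(seq_len(n), function(j) {
    if (abs(system$ub[j] - system$lb[j]) < tol) {
      return(tibble::tibble(reaction_id = system$reaction_ids[j],
                            min = unname(system$lb[j]),
                            max = unname(system$ub[j])))
    }
    obj <- replace(numeric(n), j, 1)
    lo <- solve_lp(system, obj, "min", tol)
    hi <- solve_lp(system, obj, "max", tol)
    tibble::tibble(reaction_id = system$reaction_ids[j],
                   min = lo$objective, max = hi$objective)
  })
  res
}

#' FVA optimal flux vectors (internal): the argmin/argmax vertex per
#' reaction plus the per-reaction flux ranges, used for hit-and-run
#' warmup and for pinning zero-width dimensions.
#' @noRd
fva_vertices <- function(system, tol = 1e-9) {
  n <- length(system$reaction_ids)
  cols <- vector("list", 2L * n)
  rng <- matrix(NA_real_, n, 2, dimnames = list(system$reaction_ids,
                                                c("min", "max")))
  for (j in seq_len(n)) {
    obj <- replace(numeric(n), j, 1)
    lo <- solve_lp(system, obj, "min", tol)
    hi <- solve_lp(system, obj, "max", tol)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("infeasible system while generating warmup vertices")
    }
    cols[[2L * j - 1L]] <- lo$flux
    cols[[2L * j]] <- hi$flux
    rng[j, ] <- c(lo$objective, hi$objective)
  }
  list(vertices = do.call(cbind, cols), ranges = rng)
}
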