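#' Sampler configuration
#'
#' Parameters of the hit-and-run flux sampler. `n_samples` defaults to
#' 10000 recorded points and `max_steps` to the hard ceiling of 1e10 total
#' chain steps; the effective thinning (chain steps per recorded sample)
#' defaults to `100 * (number of free dimensions)` and is capped so the
#' total never exceeds `max_steps`.
#'
#' @param n_samples Recorded samples (>= 1).
#' @param max_steps Hard ceiling on total chain steps.
#' @param seed RNG seed.
#' @param thin Steps per recorded sample; `NULL` = `100 * free_dims`.
#' @param projection_period Re-project onto the null space of S every this
#'   many recorded samples (drift control).
#' @param tolerance Mass-balance residual cap `max|Sv|` for validity.
#' @param warmup_pull Fraction by which FVA warmup vertices are pulled
#'   toward their centroid, avoiding boundary starts.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(n_samples = 10000, max_steps = 1e10, seed = 1,
                           thin = NULL, projection_period = 50,
                           tolerance = 1e-6, warmup_pull = 0.33) {
  stopifnot(n_samples >= 1, tolerance > 0, max_steps >= 1,
            warmup_pull >= 0, warmup_pull < 1)
  structure(
    list(n_samples = as.integer(n_samples), max_steps = max_steps,
         seed = as.integer(seed), thin = thin,
         projection_period = as.integer(projection_period),
         tolerance = tolerance, warmup_pull = warmup_pull),
    class = "sampler_config"
  )
}

# Geometry of the polytope: which reactions are fixed (lb == ub), a
# particular feasible point, and an orthonormal basis of the null space of
# S restricted to the free coordinates.
polytope_geometry <- function(system, tol = 1e-9) {
  n <- length(system$reaction_ids)
  fixed <- (system$ub - system$lb) < tol
  feas <- solve_lp(system, rep(0, n), "min", tol)
  if (feas$status != "optimal") {
    stop("infeasible system: the constrained flux polytope is empty")
  }
  xp <- unname(feas$flux)
  xp[fixed] <- (system$lb[fixed] + system$ub[fixed]) / 2
  S_free <- system$S[, !fixed, drop = FALSE]
  if (ncol(S_free) == 0) {
    return(list(fixed = fixed, xp = xp, N = matrix(0, 0, 0), free_dims = 0L))
  }
  sv <- svd(S_free, nu = 0, nv = ncol(S_free))
  d <- sv$d
  rank_tol <- max(dim(S_free)) * max(d, 0) * .Machine$double.eps * 100
  rank <- sum(d > rank_tol)
  N_free <- if (rank >= ncol(S_free)) {
    matrix(0, ncol(S_free), 0)
  } else {
    sv$v[, seq(rank + 1, ncol(S_free)), drop = FALSE]
  }
  list(fixed = fixed, xp = xp, N = N_free,
       free_dims = ncol(N_free))
}

#' Generate hit-and-run warmup points
#'
#' Computes the 2n flux-variability vertices (the LP minimizer and
#' maximizer of every reaction) and pulls each a configured fraction
#' toward their centroid so no chain starts exactly on the boundary.
#'
#' @param system A `stoichiometric_system`.
#' @param config A `sampler_config`.
#' @return An n x 2n matrix of feasible points (rows = reactions).
#' @export
generate_warmup <- function(system, config = sampler_config()) {
  V <- fva_vertices(system)$vertices
  center <- rowMeans(V)
  (1 - config$warmup_pull) * V + config$warmup_pull * center
}

# Pin reactions whose feasible (FVA) range has essentially zero width to
# the range midpoint. Constraints on the exchanges often force internal
# reactions onto a knife edge (range width ~0 while the declared bounds
# stay wide); leaving such dimensions free makes nearly every hit-and-run
# segment empty. Returns the tightened system plus warmup vertices with
# the pinned coordinates set exactly.
pin_zero_width <- function(system, pin_tol = 1e-9) {
  fva <- fva_vertices(system)
  rng <- fva$ranges
  scale <- pmax(1, abs(rng[, 1]), abs(rng[, 2]))
  pinned <- (rng[, 2] - rng[, 1]) < pin_tol * scale
  mid <- (rng[, 1] + rng[, 2]) / 2
  system$lb[pinned] <- mid[pinned]
  system$ub[pinned] <- mid[pinned]
  V <- fva$vertices
  V[pinned, ] <- mid[pinned]
  list(system = system, vertices = V, pinned = pinned)
}

#' Uniformly sample the flux polytope (ACHR)
#'
#' Artificially-centered hit-and-run over
#' \eqn{\{v : Sv = 0, lb \le v \le ub\}}: each iteration picks a direction
#' from a stored warmup point to the running center of all visited points,
#' computes the feasible segment from the bound crossings, steps to a
#' uniform point on it, and updates the center; the state is periodically
#' re-projected onto the null space of S to cancel numerical drift. Given
#' the same seed and system the output is bit-identical.
#'
#' @param system A `stoichiometric_system` (finite bounds).
#' @param config A `sampler_config`.
#' @param strain,time_h Optional labels carried into the result.
#' @return A `sample_set`: list with `samples` (n_samples x n_reactions
#'   matrix), `reaction_ids`, `strain`, `time_h`, `config`.
#' @export
achr_sample <- function(system, config = sampler_config(),
                        strain = NA_character_, time_h = NA_real_) {
  stopifnot(inherits(system, "stoichiometric_system"),
            inherits(config, "sampler_config"))
  n <- length(system$reaction_ids)
  pin <- pin_zero_width(system)
  sys_t <- pin$system
  geom <- polytope_geometry(sys_t)

  if (geom$free_dims == 0L) {
    warning("degenerate polytope (no free dimensions): ",
            "returning the unique feasible point")
    samples <- matrix(rep(geom$xp, each = config$n_samples),
                      nrow = config$n_samples,
                      dimnames = list(NULL, system$reaction_ids))
    return(new_sample_set(samples, system$reaction_ids, strain, time_h,
                          config))
  }

  thin <- config$thin %||% (100L * geom$free_dims)
  thin <- max(1L, min(as.integer(thin),
                      as.integer(config$max_steps %/% config$n_samples)))

  set.seed(config$seed)
  center_v <- rowMeans(pin$vertices)
  warmup <- (1 - config$warmup_pull) * pin$vertices +
    config$warmup_pull * center_v
  center0 <- rowMeans(warmup)

  # full-space projector onto the null space over the free coordinates
  P <- matrix(0, n, n)
  if (geom$free_dims > 0) {
    P[!geom$fixed, !geom$fixed] <- geom$N %*% t(geom$N)
  }
  samples <- achr_core(warmup, unname(sys_t$lb), unname(sys_t$ub),
                       start = center0, center0 = center0,
                       center_count0 = ncol(warmup),
                       n_keep = config$n_samples, thin = thin,
                       P = P, xp = geom$xp,
                       proj_period = config$projection_period,
                       dir_tol = 1e-12, inset = 1e-12)
  colnames(samples) <- system$reaction_ids
  ss <- new_sample_set(samples, system$reaction_ids, strain, time_h, config)
  rep_ok <- check_sample_validity(ss, system)
  if (rep_ok$max_abs_sv > config$tolerance) {
    stop("mass-balance residual ", format(rep_ok$max_abs_sv),
         " exceeds tolerance after projection")
  }
  ss
}

new_sample_set <- function(samples, reaction_ids, strain, time_h, config) {
  structure(
    list(samples = samples, reaction_ids = reaction_ids,
         strain = strain, time_h = time_h, config = config),
    class = "sample_set"
  )
}

#' @export
print.sample_set <- function(x, ...) {
  cat("<sample_set> ", nrow(x$samples), " samples x ",
      length(x$reaction_ids), " reactions", sep = "")
  if (!is.na(x$strain)) cat("  [", x$strain, " @ ", x$time_h, " h]", sep = "")
  cat("\n")
  invisible(x)
}

#' Tidy a sample set into a long tibble
#' @param x A `sample_set`.
#' @param ... Unused.
#' @return Tibble with `strain`, `time_h`, `sample`, `reaction_id`, `flux`.
#' @export
tidy.sample_set <- function(x, ...) {
  tibble::as_tibble(x$samples) |>
    dplyr::mutate(sample = dplyr::row_number(),
                  strain = x$strain, time_h = x$time_h) |>
    tidyr::pivot_longer(-c("sample", "strain", "time_h"),
                        names_to = "reaction_id", values_to = "flux")
}

#' Rejection-sampling oracle for small polytopes
#'
#' Exactly uniform sampling for validation: parameterizes the null space of
#' S with an orthonormal basis (so uniformity in the parameter space is
#' uniformity on the polytope), bounds each free coordinate by LP, draws
#' uniform proposals in the bounding box and keeps those satisfying all
#' flux bounds. Guarded to at most 4 free dimensions; the acceptance rate
#' decays exponentially with dimension.
#'
#' @param system A `stoichiometric_system`.
#' @param n Number of samples.
#' @param seed RNG seed.
#' @param max_free_dims Dimension guard.
#' @param batch Proposal batch size.
#' @return A `sample_set`.
#' @export
rejection_sample <- function(system, n = 10000, seed = 1,
                             max_free_dims = 4L, batch = 100000L) {
  nrx <- length(system$reaction_ids)
  system <- pin_zero_width(system)$system
  geom <- polytope_geometry(system)
  if (geom$free_dims > max_free_dims) {
    stop("rejection_sample is limited to ", max_free_dims,
         " free dimensions (this system has ", geom$free_dims, ")")
  }
  if (geom$free_dims == 0L) {
    samples <- matrix(rep(geom$xp, each = n), nrow = n,
                      dimnames = list(NULL, system$reaction_ids))
    return(new_sample_set(samples, system$reaction_ids, NA_character_,
                          NA_real_, sampler_config(n_samples = n,
                                                   seed = seed)))
  }
  free <- !geom$fixed
  N <- geom$N
  xp_free <- geom$xp[free]

  # bounding box of each null-space coordinate z_k = N_k' (v_free - xp_free)
  box <- vapply(seq_len(ncol(N)), function(k) {
    obj <- numeric(nrx)
    obj[free] <- N[, k]
    lo <- solve_lp(system, obj, "min")
    hi <- solve_lp(system, obj, "max")
    c(lo$objective, hi$objective) - sum(N[, k] * xp_free)
  }, numeric(2))

  lbf <- system$lb[free]; ubf <- system$ub[free]
  set.seed(seed)
  kept <- matrix(numeric(0), ncol = sum(free))
  proposed <- 0
  while (nrow(kept) < n) {
    Z <- vapply(seq_len(ncol(N)), function(k) {
      stats::runif(batch, box[1, k], box[2, k])
    }, numeric(batch))
    V <- Z %*% t(N)
    V <- sweep(V, 2, xp_free, "+")
    ok <- rowSums(sweep(V, 2, lbf - 1e-9, "<") |
                    sweep(V, 2, ubf + 1e-9, ">")) == 0
    proposed <- proposed + batch
    kept <- rbind(kept, V[ok, , drop = FALSE])
    if (proposed >= batch && nrow(kept) / proposed < 1e-6) {
      stop("rejection sampling acceptance rate below 1e-6; giving up ",
           "(", nrow(kept), " accepted of ", proposed, ")")
    }
  }
  kept <- kept[seq_len(n), , drop = FALSE]
  samples <- matrix(rep(geom$xp, each = n), nrow = n)
  samples[, free] <- kept
  colnames(samples) <- system$reaction_ids
  new_sample_set(samples, system$reaction_ids, NA_character_, NA_real_,
                 sampler_config(n_samples = n, seed = seed))
}

#' Chain convergence diagnostics (mean-split z-scores)
#'
#' Warning-only diagnostic in the spirit of Geweke's test: for each
#' reaction, the standardized difference between the mean of the first
#' and second halves of the chain,
#' \eqn{z = (\bar v_1 - \bar v_2) / \sqrt{s_1^2/n_1 + s_2^2/n_2}}.
#' Large |z| (say > 3 for many reactions) indicates the chain had not
#' mixed at the recorded thinning. Fixed (zero-variance) reactions
#' report z = 0.
#'
#' @param samples A `sample_set`.
#' @return Tibble with `reaction_id` and `z`; the maximum |z| is what
#'   pipelines log.
#' @export
sampling_diagnostics <- function(samples) {
  stopifnot(inherits(samples, "sample_set"))
  X <- samples$samples
  n <- nrow(X)
  if (n < 4) stop("need at least 4 samples for a mean-split diagnostic")
  half <- n %/% 2
  a <- X[seq_len(half), , drop = FALSE]
  b <- X[seq(half + 1, n), , drop = FALSE]
  se <- sqrt(apply(a, 2, stats::var) / nrow(a) +
               apply(b, 2, stats::var) / nrow(b))
  z <- ifelse(se > 0, (colMeans(a) - colMeans(b)) / se, 0)
  tibble::tibble(reaction_id = samples$reaction_ids, z = unname(z))
}

#' Validate a sample set against its system
#'
#' Reports the worst mass-balance residual `max|Sv|` and the number of
#' entries violating the flux bounds beyond the tolerance. Pipelines treat
#' any bound violation as a failure.
#'
#' @param samples A `sample_set`.
#' @param system The `stoichiometric_system` it was drawn from.
#' @param tolerance Violation tolerance.
#' @return One-row tibble: `n_samples`, `max_abs_sv`,
#'   `n_bound_violations`, `empty`.
#' @export
check_sample_validity <- function(samples, system,
                                  tolerance = samples$config$tolerance) {
  stopifnot(inherits(samples, "sample_set"),
            inherits(system, "stoichiometric_system"))
  X <- samples$samples
  if (!identical(colnames(X), system$reaction_ids)) {
    stop("sample set and system reaction ids disagree")
  }
  if (nrow(X) == 0) {
    return(tibble::tibble(n_samples = 0L, max_abs_sv = 0,
                          n_bound_violations = 0L, empty = TRUE))
  }
  resid <- system$S %*% t(X)
  below <- sweep(X, 2, unname(system$lb) - tolerance, "<")
  above <- sweep(X, 2, unname(system$ub) + tolerance, ">")
  tibble::tibble(
    n_samples = nrow(X),
    max_abs_sv = max(abs(resid)),
    n_bound_violations = sum(below) + sum(above),
    empty = FALSE
  )
}
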