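# Small analytic polytopes used across the suite.

make_system <- function(S, lb, ub) {
  structure(
    list(S = S,
         lb = stats::setNames(lb, colnames(S)),
         ub = stats::setNames(ub, colnames(S)),
         reaction_ids = colnames(S),
         metabolite_ids = rownames(S)),
    class = "stoichiometric_system"
  )
}

# linear chain EX_A -> R1 -> EX_B; one free dimension, the through-flux is
# uniform on [0, 10]
chain_system <- function() {
  S <- matrix(c(-1, -1, 0,
                0, 1, -1),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("EX_A", "R1", "EX_B")))
  make_system(S, c(-10, 0, 0), c(0, 10, 10))
}

# fixed input of 10 split across three identical branches; two free
# dimensions, uniform on the scaled 2-simplex (each branch marginal has
# mean 10/3 and variance 100/18)
simplex_system <- function() {
  S <- matrix(c(1, -1, -1, -1), nrow = 1,
              dimnames = list("M", c("IN", "B1", "B2", "B3")))
  make_system(S, c(10, 0, 0, 0), c(10, 10, 10, 10))
}

# every reaction pinned: the polytope is a single point
fixed_system <- function() {
  S <- matrix(c(-1, -1, 0,
                0, 1, -1),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("EX_A", "R1", "EX_B")))
  make_system(S, c(-4, 4, 4), c(-4, 4, 4))
}

# tiny hand-built model: A imported, converted to B, B exported
chain_model <- function() {
  metabolic_model(
    "chain",
    tibble::tibble(id = c("A", "B"), name = c("A", "B"),
                   compartment = "c"),
    tibble::tibble(
      id = c("EX_A", "R1", "EX_B"),
      name = c("A exchange", "conversion", "B exchange"),
      lower_bound = c(-10, 0, 0), upper_bound = c(0, 10, 10),
      gene_association = c("", "G1", ""),
      subsystem = c("Exchange", "Core", "Exchange"),
      stoichiometry = list(c(A = -1), c(A = -1, B = 1), c(B = -1))
    )
  )
}

expect_samples_valid <- function(ss, sys, tol = 1e-6) {
  rep <- check_sample_validity(ss, sys, tolerance = tol)
  expect_equal(rep$n_bound_violations, 0L)
  expect_lt(rep$max_abs_sv, tol)
}
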