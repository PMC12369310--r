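#' Scalar product between L2-normalized non-negative vectors
#'
#' The similarity measure used throughout: both vectors are scaled to unit
#' L2 norm and their dot product taken, giving a value in `[0, 1]` for
#' non-negative inputs.
#'
#' @param u,v Non-negative numeric vectors of equal length, each with at
#'   least one non-zero entry.
#' @return Scalar in `[0, 1]`.
#' @examples
#' scalar_product(c(1, 1, 0), c(1, 0, 1))  # 0.5
#' @export
scalar_product <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("scalar product undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

# All pairwise scalar products between the columns of A and B.
similarity_matrix <- function(A, B) {
  An <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  Bn <- sweep(B, 2, sqrt(colSums(B^2)), "/")
  t(An) %*% Bn
}

#' Preferred field-synergy pairs within a condition
#'
#' Computes the scalar product between every unit's muscle field and every
#' muscle synergy of the same condition; the pair with the highest scalar
#' product is the unit's "preferred pair". Argmax ties are broken toward
#' the lowest synergy index (and reported via the `tie` column).
#'
#' @param fields Output of [build_muscle_field()] (one condition's rows are
#'   used).
#' @param fit A `"synergy_fit"` for the same condition.
#' @param condition Condition label to select from `fields`.
#' @return Tibble with one row per unit x synergy: `unit_id`, `condition`,
#'   `synergy`, `sp`, `preferred` (logical), `tie` (logical).
#' @export
preferred_pairs <- function(fields, fit, condition = fit$condition) {
  stopifnot(inherits(fit, "synergy_fit"))
  if (is.na(condition)) condition <- unique(fields$condition)[1]
  zeros <- unique(fields$unit_id[fields$condition == condition & fields$all_zero])
  if (length(zeros)) {
    warning("excluding all-zero muscle field(s): ", paste(zeros, collapse = ", "))
  }
  fm <- field_matrix(fields, condition, muscles = fit$muscles)
  S <- similarity_matrix(fm, fit$W)  # units x synergies
  purrr::map_dfr(seq_len(nrow(S)), function(i) {
    best <- which.max(S[i, ])  # ties -> lowest index
    tibble::tibble(
      unit_id = rownames(S)[i] %||% colnames(fm)[i],
      condition = condition,
      synergy = seq_len(ncol(S)),
      sp = as.numeric(S[i, ]),
      preferred = seq_len(ncol(S)) == best,
      tie = sum(S[i, ] == S[i, best]) > 1
    )
  })
}

#' Match two sets of vectors across conditions
#'
#' One-to-one assignment between the columns of `A` and `B` (muscle fields
#' or muscle synergies from two stimulation conditions) maximizing the total
#' scalar product, solved by the Hungarian algorithm. When the sets differ
#' in size, the smaller set is fully assigned.
#'
#' @param A,B Non-negative matrices `[n_muscles x N_A]`, `[n_muscles x N_B]`.
#' @return Tibble with columns `index_a`, `index_b`, `sp`, carrying the mean
#'   pairwise scalar product as attribute `"mean_sp"`.
#' @export
match_across_conditions <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(nrow(A) == nrow(B), ncol(A) >= 1, ncol(B) >= 1)
  S <- similarity_matrix(A, B)
  flipped <- FALSE
  if (nrow(S) > ncol(S)) { S <- t(S); flipped <- TRUE }
  sol <- clue::solve_LSAP(S, maximum = TRUE)
  ia <- seq_len(nrow(S)); ib <- as.integer(sol)
  if (flipped) { tmp <- ia; ia <- ib; ib <- tmp; S <- t(S) }
  out <- tibble::tibble(index_a = ia, index_b = ib,
                        sp = S[cbind(ia, ib)]) |>
    dplyr::arrange(.data$index_a)
  attr(out, "mean_sp") <- mean(out$sp)
  out
}

#' Across-condition consistency rate
#'
#' Fraction of matched pairs whose scalar product reaches the consistency
#' threshold (default 0.78).
#'
#' @param matches Tibble from [match_across_conditions()] (needs an `sp`
#'   column).
#' @param threshold Scalar-product cut-off.
#' @return Fraction in `[0, 1]`, or `NA` for an empty input.
#' @export
consistency_rate <- function(matches, threshold = 0.78) {
  if (!nrow(matches)) return(NA_real_)
  mean(matches$sp >= threshold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
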