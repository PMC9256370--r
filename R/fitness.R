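#' Size of the feature-subset search space
#'
#' A wrapper search over `x` binary inclusion decisions has `2^x` candidate
#' subsets. Exact for any `x`: the result is returned as a numeric when it is
#' exactly representable in a double (`x <= 53`) and as a decimal string
#' otherwise.
#'
#' @param x Number of features (non-negative integer).
#' @return `2^x`, numeric for `x <= 53`, character otherwise.
#' @export
search_space_size <- function(x) {
  stopifnot(length(x) == 1L, x >= 0, x == round(x))
  if (x <= 53) return(2^x)
  # schoolbook doubling on a base-10 digit vector, least-significant first
  digits <- c(1L)
  for (i in seq_len(x)) {
    digits <- digits * 2L
    carry <- 0L
    for (j in seq_along(digits)) {
      v <- digits[j] + carry
      digits[j] <- v %% 10L
      carry <- v %/% 10L
    }
    while (carry > 0L) {
      digits <- c(digits, carry %% 10L)
      carry <- carry %/% 10L
    }
  }
  paste(rev(digits), collapse = "")
}

#' Weights of the subset fitness function
#'
#' The wrapper objective scores a candidate subset `A` with classification
#' accuracy `J(A)` as `f(A) = m * J(A) + n / |A|`: high accuracy is rewarded
#' and, between subsets of similar accuracy, the smaller one wins. The
#' default weights `m = 0.92`, `n = 0.78` prioritize accuracy while keeping a
#' meaningful parsimony bonus.
#'
#' @param m_weight Accuracy weight in `[0, 1]`.
#' @param n_weight Parsimony weight in `[0, 1]`.
#' @return A `fitness_config` list.
#' @export
fitness_config <- function(m_weight = 0.92, n_weight = 0.78) {
  stopifnot(m_weight >= 0, m_weight <= 1, n_weight >= 0, n_weight <= 1)
  structure(list(m_weight = m_weight, n_weight = n_weight),
            class = "fitness_config")
}

#' Evaluate the subset fitness function
#'
#' @param accuracy Classification accuracy `J` in `[0, 1]`.
#' @param n_selected Number of selected features, `>= 1`.
#' @param fc A [fitness_config()].
#' @return `m_weight * accuracy + n_weight / n_selected`.
#' @export
subset_fitness <- function(accuracy, n_selected, fc = fitness_config()) {
  stopifnot(inherits(fc, "fitness_config"))
  if (any(n_selected < 1)) stop("a subset must contain at least one feature")
  if (any(accuracy < 0 | accuracy > 1)) stop("accuracy must lie in [0, 1]")
  fc$m_weight * accuracy + fc$n_weight / n_selected
}
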