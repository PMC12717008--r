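#' Colour difference and R-Index sensory discrimination
#'
#' The CIELAB colour-difference metric used to quantify fortification-induced
#' colour change, and the R-Index multiple-difference analysis of 4-category
#' confidence ratings (reference sure / reference unsure / not-reference
#' unsure / not-reference sure) with permutation-based critical values.
#'
#' @name sensometrics
NULL

#' CIELAB colour difference Delta E*ab
#'
#' Euclidean distance in CIELAB space:
#' `sqrt(dL^2 + da^2 + db^2)` between a sample and its reference.
#'
#' @param sample,reference numeric `c(L, a, b)` triples.
#' @return non-negative colour difference.
#' @export
#' @examples
#' delta_e_ab(c(53, 4, 0), c(50, 0, 0)) # 5
delta_e_ab <- function(sample, reference) {
  if (length(sample) != 3 || length(reference) != 3) {
    stop("colours are (L*, a*, b*) triples")
  }
  if (any(!is.finite(sample)) || any(!is.finite(reference))) {
    stop("colour coordinates must be finite")
  }
  sqrt(sum((as.numeric(sample) - as.numeric(reference))^2))
}

#' R-Index from 4-category confidence counts
#'
#' Counts are ordered most-"different" first: (not-reference sure,
#' not-reference unsure, reference unsure, reference sure). The R-Index is
#' 100 times the probability that a randomly chosen test rating is judged
#' more "different" than a randomly chosen reference rating, ties counted
#' half:
#' `R = 100 * (sum_{i<j} t_i r_j + 0.5 * sum_i t_i r_i) / (T * R)`.
#' 50 is the random-guessing expectation; 100 is perfect discrimination.
#'
#' @param test_counts,ref_counts non-negative integer vectors of equal
#'   length (4 categories in the standard protocol), most-"different"
#'   category first.
#' @return list with `r_index` (0--100), `n_test`, `n_ref`.
#' @export
#' @examples
#' r_index(c(1, 0, 1, 0), c(0, 1, 0, 1))$r_index # 75
r_index <- function(test_counts, ref_counts) {
  if (length(test_counts) != length(ref_counts)) {
    stop("count vectors must have equal length")
  }
  if (any(test_counts < 0) || any(ref_counts < 0)) {
    stop("counts must be non-negative")
  }
  n_t <- sum(test_counts); n_r <- sum(ref_counts)
  if (n_t == 0 || n_r == 0) stop("both rating rows must have positive totals")
  k <- length(test_counts)
  wins <- 0
  for (i in seq_len(k - 1)) {
    wins <- wins + test_counts[i] * sum(ref_counts[(i + 1):k])
  }
  ties <- sum(test_counts * ref_counts)
  list(r_index = 100 * (wins + 0.5 * ties) / (n_t * n_r),
       n_test = n_t, n_ref = n_r)
}

# R statistic from tieless ranks assigned to the test group:
# U / (n_t * n_r) scaled to 0..100
.r_from_ranks <- function(test_ranks, n_test, n_ref) {
  u <- sum(test_ranks) - n_test * (n_test + 1) / 2
  100 * u / (n_test * n_ref)
}

#' Critical value of the R-Index under the exchangeable null
#'
#' Smallest value `c` such that `P(R >= c) <= alpha` when all
#' `n_test + n_ref` ratings are exchangeable between the test and reference
#' labels. The null distribution is built by permuting rating ranks between
#' the two labels: exactly (full enumeration of all label assignments, small
#' totals only) or by Monte-Carlo (default 200,000 draws). With no tie
#' structure imposed, R reduces to the scaled rank-sum statistic, which makes
#' the permutation null free of any parametric rating assumption.
#'
#' @param n_test,n_ref rating totals (>= 1 each).
#' @param alpha one-sided significance level.
#' @param method `"montecarlo"` (default) or `"exact"`.
#' @param n_draws Monte-Carlo permutation count.
#' @param seed integer seed for the Monte-Carlo method.
#' @param exact_budget refuse exact enumeration beyond this many label
#'   assignments.
#' @return the critical R-Index value on the 0--100 scale.
#' @export
r_index_critical <- function(n_test, n_ref, alpha = 0.05,
                             method = c("montecarlo", "exact"),
                             n_draws = 200000, seed = 1,
                             exact_budget = 5e5) {
  method <- match.arg(method)
  if (n_test < 1 || n_ref < 1) stop("rating totals must be at least 1")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  n <- n_test + n_ref
  if (method == "exact") {
    if (choose(n, n_test) > exact_budget) {
      stop(sprintf(
        "exact enumeration of %.3g assignments exceeds the budget (%g)",
        choose(n, n_test), exact_budget))
    }
    assigns <- utils::combn(n, n_test)
    rs <- apply(assigns, 2, .r_from_ranks, n_test = n_test, n_ref = n_ref)
  } else {
    rs <- withr_seed(seed, {
      vapply(seq_len(n_draws), function(i) {
        .r_from_ranks(sample.int(n, n_test), n_test, n_ref)
      }, numeric(1))
    })
  }
  # smallest achievable value c with P(R >= c) <= alpha
  vals <- sort(unique(rs))
  exceed <- vapply(vals, function(v) mean(rs >= v), numeric(1))
  ok <- vals[exceed <= alpha]
  if (!length(ok)) return(100)
  min(ok)
}

#' Classify an R-Index against its critical value
#'
#' One-sided decision: the sample is called perceptibly different from the
#' reference iff the R-Index strictly exceeds the critical value (a value
#' exactly at the threshold is not called different).
#'
#' @param r_index_value observed R-Index (0--100).
#' @param critical_value from [r_index_critical()].
#' @return list with logical `significant` and a `label`.
#' @export
classify_difference <- function(r_index_value, critical_value) {
  sig <- r_index_value > critical_value
  list(significant = sig,
       label = if (sig) "perceptibly different" else "not distinguished")
}
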