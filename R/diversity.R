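#' Proportional clone abundances under a size metric
#'
#' Applies an instance cut-off (clones with fewer instances are dropped)
#' and renormalizes the chosen size metric over the surviving clones,
#' yielding the abundance vector p that all diversity and evenness
#' statistics consume.
#'
#' @param clones Clone tibble from [assign_clones()].
#' @param metric One of `"copies"`, `"instances"`, `"uniques"`.
#' @param min_instances Instance cut-off; clones with
#'   `instances < min_instances` are excluded (default 1 keeps all).
#' @return Numeric vector of abundances summing to 1, named by clone id,
#'   with attribute `metric`.
#' @export
abundance_from_clones <- function(clones,
                                  metric = c("copies", "instances",
                                             "uniques"),
                                  min_instances = 1L) {
  metric <- match.arg(metric)
  keep <- clones$instances >= min_instances
  if (!any(keep)) {
    stop("instance cut-off ", min_instances, " excludes every clone",
         call. = FALSE)
  }
  x <- clones[[metric]][keep]
  p <- x / sum(x)
  names(p) <- clones$clone_id[keep]
  attr(p, "metric") <- metric
  p
}

check_abundance <- function(p) {
  if (length(p) == 0L || any(p <= 0)) {
    stop("abundance vector must be non-empty with strictly positive ",
         "entries", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop("abundances must sum to 1 (got ", format(sum(p)), ")",
         call. = FALSE)
  }
  invisible(p)
}

#' Hill-number (true) diversity of order q
#'
#' `(sum_i p_i^q)^(1/(1-q))` for q != 1, with the continuous limit
#' `exp(-sum_i p_i log p_i)` at q = 1 (evaluated for |q - 1| <= 1e-9).
#' Order 0 gives the richness, order 1 the exponential of the Shannon
#' entropy, and order 2 the inverse Simpson index; higher orders weight
#' large clones more heavily.
#'
#' @param p Abundance vector (positive, summing to 1), e.g. from
#'   [abundance_from_clones()].
#' @param q Diversity order, non-negative real.
#' @return The effective number of clones, in \[1, R\].
#' @examples
#' hill_diversity(c(0.5, 0.25, 0.25), q = 2)
#' @export
hill_diversity <- function(p, q) {
  check_abundance(p)
  if (q < 0) stop("diversity order q must be >= 0", call. = FALSE)
  if (abs(q - 1) <= 1e-9) {
    exp(-sum(p * log(p)))
  } else {
    sum(p^q)^(1 / (1 - q))
  }
}

#' Diversity profile over a grid of orders
#'
#' Evaluates [hill_diversity()] at each order; the default grid is 0 to 4
#' in steps of 0.1 (which includes the integer Hill numbers 0 through 4).
#' The profile is non-increasing in q.
#'
#' @inheritParams hill_diversity
#' @param orders Ascending numeric vector of orders (default
#'   `seq(0, 4, by = 0.1)`).
#' @return Tibble `q`, `diversity`.
#' @export
diversity_profile <- function(p, orders = seq(0, 4, by = 0.1)) {
  stopifnot(!is.unsorted(orders))
  tibble::tibble(
    q = orders,
    diversity = vapply(orders, function(q) hill_diversity(p, q),
                       numeric(1))
  )
}

#' Shannon entropy of clone abundances
#'
#' `H = -sum_i p_i log p_i` (natural logarithm). Approaches 0 for a
#' monoclonal sample and log(R) when all R clones are equally abundant.
#'
#' @inheritParams hill_diversity
#' @return Entropy in nats.
#' @export
shannon <- function(p) {
  check_abundance(p)
  -sum(p * log(p))
}

#' Simpson's index of clone abundances
#'
#' `lambda = sum_i p_i^2`: the probability that two individuals drawn at
#' random belong to the same clone. Equals the reciprocal of the Hill
#' diversity of order 2.
#'
#' @inheritParams hill_diversity
#' @return Value in (0, 1\].
#' @export
simpson <- function(p) {
  check_abundance(p)
  sum(p^2)
}

#' Pielou's evenness of clone abundances
#'
#' `J = H / log(R)`, in \[0, 1\]: 1 when all clones are the same size,
#' approaching 0 when one clone dominates. Undefined for a single clone
#' (log 1 = 0); in that case `NA` is returned with a warning.
#'
#' @inheritParams hill_diversity
#' @return Evenness in \[0, 1\], or `NA` when R = 1.
#' @export
pielou <- function(p) {
  check_abundance(p)
  if (length(p) < 2L) {
    warning("Pielou's evenness is undefined for a single clone",
            call. = FALSE)
    return(NA_real_)
  }
  shannon(p) / log(length(p))
}

#' Clonality of a repertoire
#'
#' `C = 1 - J` where J is Pielou's evenness: 0 for a maximally even
#' repertoire, approaching 1 as one clone takes over. Undefined for a
#' single clone.
#'
#' @inheritParams hill_diversity
#' @return Clonality in \[0, 1\], or `NA` when R = 1.
#' @export
clonality <- function(p) {
  1 - pielou(p)
}

#' Diversity summary at instance cut-offs
#'
#' Convenience wrapper computing richness, Shannon entropy, Simpson's
#' index, Pielou's evenness and clonality for each combination of size
#' metric and instance cut-off.
#'
#' @param clones Clone tibble from [assign_clones()].
#' @param metrics Size metrics to evaluate.
#' @param cutoffs Instance cut-offs to evaluate.
#' @return Tibble with one row per metric x cut-off.
#' @export
diversity_summary <- function(clones,
                              metrics = c("copies", "instances",
                                          "uniques"),
                              cutoffs = 1L) {
  grid <- expand.grid(metric = metrics, cutoff = cutoffs,
                      stringsAsFactors = FALSE)
  purrr::pmap_dfr(grid, function(metric, cutoff) {
    p <- abundance_from_clones(clones, metric, cutoff)
    j <- if (length(p) >= 2L) pielou(p) else NA_real_
    tibble::tibble(
      metric = metric, cutoff = cutoff, richness = length(p),
      shannon = shannon(p), simpson = simpson(p),
      pielou = j, clonality = 1 - j
    )
  })
}
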