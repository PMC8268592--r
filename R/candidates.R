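#' Enumerate candidate regulatory interactions for one step
#'
#' A step-`n` candidate pairs a flux with a set of `n` metabolites that is
#' hypothesised to fully determine it. Every candidate set contains the
#' reaction's primary substrate, so each active flux contributes
#' `choose(m - 1, n - 1)` candidates over `m` metabolites. Order is
#' deterministic: by reaction id (network order), then lexicographic over
#' controller sets.
#'
#' @param net a [scour_network].
#' @param n step order (1, 2 or 3).
#' @param active_fluxes reaction ids still under consideration; defaults
#'   to all non-constant reactions. Fluxes positively identified at an
#'   earlier step are dropped from this set by the stepwise driver.
#' @return A list of candidates, each a list with `reaction_id`,
#'   `controllers` (sorted character vector of size `n`) and `order`.
#' @export
#' @examples
#' net <- reference_network("smaller")
#' length(enumerate_candidates(net, 2))        # 25
#' length(enumerate_candidates(net, 2,
#'        setdiff(reaction_ids(net, constant = FALSE), "v2")))  # 20
enumerate_candidates <- function(net, n, active_fluxes = NULL) {
  stopifnot(n %in% 1:3)
  noncon <- reaction_ids(net, constant = FALSE)
  if (is.null(active_fluxes)) active_fluxes <- noncon
  if (!all(active_fluxes %in% noncon)) {
    stop("active_fluxes must be non-constant reaction ids", call. = FALSE)
  }
  out <- list()
  for (rid in noncon[noncon %in% active_fluxes]) {
    r <- get_reaction(net, rid)
    s <- r$substrate
    others <- sort(setdiff(net$metabolites, s))
    if (n - 1 > length(others)) next
    sets <- if (n == 1) list(character()) else {
      combs <- utils::combn(others, n - 1, simplify = FALSE)
      combs
    }
    for (tt in sets) {
      out[[length(out) + 1L]] <- list(
        reaction_id = rid,
        controllers = sort(c(s, tt)),
        order = as.integer(n)
      )
    }
  }
  out
}

## Is a candidate the exact ground-truth interaction for its flux?
## TRUE iff its controller set equals the flux's true controller set and
## the true order equals the candidate order.
candidate_is_true <- function(net, cand) {
  r <- get_reaction(net, cand$reaction_id)
  truth <- sort(names(r$controllers))
  length(truth) == cand$order && identical(sort(cand$controllers), truth)
}
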