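## Year-stratified novelty: contemporary and current singleton rates.

# Neighbour pairs (dice >= cutoff) with years attached; compounds with a
# missing year are excluded upstream.
.year_lookup <- function(network) {
  stats::setNames(network$compounds$year, network$compounds$compound_id)
}

.check_years <- function(network) {
  missing_year <- network$compounds$compound_id[is.na(network$compounds$year)]
  if (length(missing_year) == nrow(network$compounds))
    rlang::abort("no compound has a year of first report")
  missing_year
}

#' Contemporary singletons: novel at their time of discovery
#'
#' A compound reported in year *y* is a contemporary singleton when no
#' compound from a strictly earlier year is similar to it (Dice at or
#' above the network cutoff). Compounds of the same year are not compared
#' to each other under the default strict reading; set
#' `include_same_year = TRUE` to also count same-year neighbours.
#' Compounds of the earliest year are contemporary singletons vacuously.
#'
#' @param network An `np_network` object whose compounds carry years.
#' @param include_same_year Also treat same-year neighbours as prior art
#'   (default `FALSE`).
#' @return A tibble with columns `year`, `compound_id`, one row per
#'   contemporary singleton; compounds without a year are skipped and
#'   listed in the `"excluded"` attribute.
#' @export
contemporary_singletons <- function(network, include_same_year = FALSE) {
  stopifnot(inherits(network, "np_network"))
  excluded <- .check_years(network)
  year <- .year_lookup(network)
  edges <- network$edges
  not_novel <- character(0)
  if (nrow(edges) > 0) {
    ya <- year[edges$id_a]; yb <- year[edges$id_b]
    ok <- !is.na(ya) & !is.na(yb)
    cmp <- if (include_same_year) `<=` else `<`
    not_novel <- unique(c(edges$id_b[ok & cmp(ya, yb)],
                          edges$id_a[ok & cmp(yb, ya)]))
  }
  ids <- setdiff(network$compounds$compound_id[!is.na(network$compounds$year)],
                 not_novel)
  out <- tibble::tibble(year = unname(year[ids]), compound_id = ids) |>
    dplyr::arrange(.data$year, .data$compound_id)
  attr(out, "excluded") <- excluded
  out
}

#' Current singletons: still novel against the whole collection
#'
#' A compound is a current singleton when no other compound in the
#' collection — any year, self-comparison excluded — is similar to it at
#' the cutoff; equivalently, when it forms a size-1 cluster of the
#' similarity network.
#'
#' @inheritParams contemporary_singletons
#' @return A tibble with columns `year`, `compound_id`, one row per
#'   current singleton with a known year; the `"excluded"` attribute
#'   lists compounds without a year.
#' @export
current_singletons <- function(network) {
  stopifnot(inherits(network, "np_network"))
  excluded <- .check_years(network)
  year <- .year_lookup(network)
  ids <- network$clusters$compound_id[network$clusters$cluster_size == 1]
  ids <- ids[!is.na(year[ids])]
  out <- tibble::tibble(year = unname(year[ids]), compound_id = ids) |>
    dplyr::arrange(.data$year, .data$compound_id)
  attr(out, "excluded") <- excluded
  out
}

#' Year-by-year novelty timeline
#'
#' Assembles, for every year with at least one discovery, the number of
#' compounds reported, the contemporary-singleton and current-singleton
#' counts, and the corresponding percentages. The contemporary percentage
#' bounds the current one from above in every year, since a compound that
#' is still unmatched today was necessarily unmatched at discovery.
#'
#' @inheritParams contemporary_singletons
#' @return A tibble of class `np_timeline` with columns `year`,
#'   `n_discovered`, `n_contemporary_singletons`, `n_current_singletons`,
#'   `pct_contemporary`, `pct_current`, sorted by year; years with zero
#'   discoveries are omitted.
#' @export
novelty_timeline <- function(network, include_same_year = FALSE) {
  stopifnot(inherits(network, "np_network"))
  if (nrow(network$compounds) == 0 || all(is.na(network$compounds$year))) {
    out <- tibble::tibble(
      year = integer(0), n_discovered = integer(0),
      n_contemporary_singletons = integer(0), n_current_singletons = integer(0),
      pct_contemporary = numeric(0), pct_current = numeric(0))
    class(out) <- c("np_timeline", class(out))
    return(out)
  }
  contemp <- contemporary_singletons(network, include_same_year = include_same_year)
  current <- current_singletons(network)
  years <- network$compounds$year[!is.na(network$compounds$year)]
  out <- tibble::tibble(year = sort(unique(years))) |>
    dplyr::mutate(
      n_discovered = vapply(.data$year, function(y) sum(years == y), integer(1)),
      n_contemporary_singletons = vapply(.data$year, function(y)
        sum(contemp$year == y), integer(1)),
      n_current_singletons = vapply(.data$year, function(y)
        sum(current$year == y), integer(1)),
      pct_contemporary = round(100 * .data$n_contemporary_singletons /
                                 .data$n_discovered, 1),
      pct_current = round(100 * .data$n_current_singletons /
                            .data$n_discovered, 1))
  attr(out, "excluded") <- attr(contemp, "excluded")
  class(out) <- c("np_timeline", class(out))
  out
}
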