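#' Expand coalition events into dyadic records
#'
#' A coalition of two actor males yields one dyadic record; a coalition of
#' three is treated as three pairwise coalitions (all actor dyads, same
#' date).
#'
#' @param coalitions coalition tibble (`date`, `actor_ids` `;`-separated,
#'   `target_ids`, `aggression_type`).
#' @return tibble `date`, `year`, `id_a`, `id_b` (one row per dyadic
#'   coalition).
#' @export
dyadize_coalitions <- function(coalitions) {
  actors <- strsplit(coalitions$actor_ids, ";", fixed = TRUE)
  if (any(!lengths(actors) %in% c(2L, 3L))) {
    stop("coalitions must have 2 or 3 actors")
  }
  rows <- purrr::map2(actors, seq_along(actors), function(a, i) {
    cmb <- combn(sort(a), 2)
    tibble::tibble(date = coalitions$date[i], id_a = cmb[1, ], id_b = cmb[2, ])
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(year = as.integer(format(.data$date, "%Y")), .after = "date")
}

#' Yearly coalition networks
#'
#' One network per calendar year from dyadic coalition records; years in
#' which fewer than `min_dyads` distinct dyads formed coalitions are
#' dropped (too sparse for differentiated betweenness), with a message.
#'
#' @param dyadic output of [dyadize_coalitions()].
#' @param min_dyads minimum number of distinct coalition dyads a year must
#'   have to be retained.
#' @return tibble `year`, `id_a`, `id_b`, `n_events` (edge list, one row
#'   per dyad-year).
#' @export
build_yearly_networks <- function(dyadic, min_dyads = 8) {
  edges <- dyadic |>
    dplyr::count(.data$year, .data$id_a, .data$id_b, name = "n_events")
  keep <- edges |>
    dplyr::count(.data$year, name = "n_dyads") |>
    dplyr::filter(.data$n_dyads >= min_dyads)
  dropped <- setdiff(unique(edges$year), keep$year)
  if (length(dropped)) {
    message("dropping sparse coalition year(s): ",
            paste(sort(dropped), collapse = ", "))
  }
  dplyr::semi_join(edges, keep, by = "year")
}

#' Betweenness centrality in coalition networks
#'
#' Unweighted shortest-path betweenness (raw pair counts, unnormalized) on
#' the binary coalition graph of each year: an edge joins two males with at
#' least one dyadic coalition. Disconnected components contribute only
#' reachable pairs.
#'
#' @param networks edge-list tibble from [build_yearly_networks()].
#' @param weighted use inverse coalition counts as edge lengths.
#' @param normalized divide by the number of ordered pairs excluding the
#'   vertex.
#' @return tibble `year`, `id`, `betweenness`.
#' @export
coalition_betweenness <- function(networks, weighted = FALSE,
                                  normalized = FALSE) {
  networks |>
    dplyr::group_by(.data$year) |>
    dplyr::group_modify(function(ed, key) {
      g <- igraph::graph_from_data_frame(
        ed[, c("id_a", "id_b")], directed = FALSE)
      w <- if (weighted) 1 / ed$n_events else NA
      b <- igraph::betweenness(g, weights = w, normalized = normalized)
      tibble::tibble(id = names(b), betweenness = unname(b))
    }) |>
    dplyr::ungroup()
}

#' Regress coalitionary betweenness on strong association ties
#'
#' Ordinary least squares of yearly betweenness on the count of strong
#' association ties, the tie counts Z-scaled within each year to absorb
#' varying community size.
#'
#' @param data tibble with `year`, `id`, `betweenness`,
#'   `n_strong_assoc_ties` (one row per male-year).
#' @return a `ties_betweenness_fit` wrapping the `lm` fit; see
#'   [tidy()]/[glance()] for slope, 95% CI and F.
#' @export
betweenness_vs_strong_ties <- function(data) {
  if (nrow(data) < 3) stop("need at least 3 male-year observations")
  data <- data |>
    dplyr::group_by(.data$year) |>
    dplyr::mutate(ties_z = suppressWarnings(
      z_standardize(.data$n_strong_assoc_ties))) |>
    dplyr::ungroup()
  fit <- lm(betweenness ~ ties_z, data = data)
  perfect <- isTRUE(suppressWarnings(summary(fit))$sigma < 1e-10)
  if (perfect) warning("betweenness_vs_strong_ties: perfect fit (zero residual)")
  structure(list(fit = fit, data = data, perfect = perfect),
            class = "ties_betweenness_fit")
}

#' @export
tidy.ties_betweenness_fit <- function(x, conf.level = 0.95, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  ci <- confint(x$fit, level = conf.level)
  tibble::tibble(
    term = rownames(s),
    estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4],
    conf.low = ci[, 1], conf.high = ci[, 2]
  )
}

#' @export
glance.ties_betweenness_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))
  tibble::tibble(
    slope = unname(coef(x$fit)[2]),
    f.statistic = unname(s$fstatistic["value"]),
    p.value = unname(stats::pf(s$fstatistic["value"], s$fstatistic["numdf"],
                               s$fstatistic["dendf"], lower.tail = FALSE)),
    r.squared = s$r.squared,
    nobs = nrow(x$data),
    perfect_fit = x$perfect
  )
}

#' @export
print.ties_betweenness_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<ties_betweenness_fit> slope = %.4f, F = %.2f, p = %.3g, n = %d\n",
    g$slope, g$f.statistic, g$p.value, g$nobs))
  invisible(x)
}
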