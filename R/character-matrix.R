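# Characters for phylogenetic analysis come in two kinds:
#   association    -- a set of >=2 human chromosomes sharing one target
#                     chromosome; the state is the occurrence count per
#                     haploid complement (0 = absent, 2 = e.g. "12/22 twice")
#   fragment_count -- the number of blocks one human chromosome paints
#                     (1 = conserved intact)
# States are stored as [state_min, state_max] intervals with a status of
# "observed" (point value), "range" (printed "?" bounds) or "missing".

#' Extract syntenic associations from a painting map
#'
#' One row per association occurrence: each chromosome painted by two or more
#' distinct human chromosomes yields its maximal association (triples are kept
#' as triples, never decomposed into pairs).
#'
#' @param map A [painting_map()].
#' @return Tibble with columns `chrom_id`, `association`, `n_members`,
#'   `uncertain` (the occurrence rests on a "?" segment or chromosome).
#' @examples
#' extract_associations(xen_painting_maps()$BTO)
#' @export
extract_associations <- function(map) {
  unc_chr <- map$chromosomes$chrom_id[map$chromosomes$uncertain_chrom]
  map$segments |>
    group_by(.data$chrom_id) |>
    summarise(
      members = list(unique(.data$hsa)),
      # uncertain if a segment needed for multi-probe status is itself "?"
      uncertain = any(.data$uncertain[!duplicated(.data$hsa)]) ||
        dplyr::first(.data$chrom_id) %in% unc_chr
    ) |>
    ungroup() |>
    filter(lengths(.data$members) >= 2) |>
    mutate(association = purrr::map_chr(.data$members, association_id),
           n_members = lengths(.data$members)) |>
    select("chrom_id", "association", "n_members", "uncertain") |>
    arrange(.data$association, .data$chrom_id)
}

#' Extract fragment counts from a painting map
#'
#' Number of blocks each human chromosome paints, as an interval: uncertain
#' ("?") segments and chromosomes widen `count_max` but not `count_min`.
#' Failed probes give a missing count.
#'
#' @param map A [painting_map()].
#' @return Tibble with columns `hsa`, `count_min`, `count_max`, `status`.
#' @export
extract_fragment_counts <- function(map) {
  unc_chr <- map$chromosomes$chrom_id[map$chromosomes$uncertain_chrom]
  seg <- filter(map$segments, .data$hsa != "Y") |>
    mutate(unc = .data$uncertain | .data$chrom_id %in% unc_chr)
  universe <- setdiff(HSA_LEVELS, "Y")
  counts <- seg |>
    group_by(.data$hsa) |>
    summarise(count_min = sum(!.data$unc), count_max = n()) |>
    ungroup()
  tibble(hsa = universe) |>
    left_join(counts, by = "hsa") |>
    mutate(
      count_min = if_else(is.na(.data$count_min), 0L, as.integer(.data$count_min)),
      count_max = if_else(is.na(.data$count_max), 0L, as.integer(.data$count_max)),
      count_min = if_else(.data$hsa %in% map$probes_failed, NA_integer_, .data$count_min),
      count_max = if_else(.data$hsa %in% map$probes_failed, NA_integer_, .data$count_max),
      status = dplyr::case_when(
        .data$hsa %in% map$probes_failed ~ "missing",
        .data$count_min == .data$count_max ~ "observed",
        TRUE ~ "range"
      )
    )
}

as_character_matrix <- function(tab, policy) {
  chars <- distinct(tab, .data$character, .data$kind) |> arrange(.data$character)
  structure(
    tab,
    taxa = unique(tab$taxon),
    characters = chars,
    uncertainty_policy = policy,
    class = c("karyo_matrix", class(tibble())))
}

#' Build a character matrix from painting maps
#'
#' Association characters are the union of all association identities seen in
#' any map (state = occurrence count); fragment-count characters are one per
#' human chromosome. The uncertainty policy governs "?" entries: `"missing"`
#' leaves presence unknown, `"optimistic"` scores the printed value,
#' `"pessimistic"` scores the minimum. Failed probes are always missing.
#'
#' @param maps Named list of [painting_map()] objects (names = taxa).
#' @param policy `"missing"`, `"optimistic"` or `"pessimistic"`.
#' @param contains Character vector of association identities scored by
#'   containment: a taxon whose larger association includes all the members
#'   (e.g. Tamandua's 7/10/20 for the 7/10 character) counts as bearing it.
#'   All other characters require an exact identity match.
#' @return A long tibble of class `karyo_matrix` with columns `taxon`,
#'   `character`, `kind`, `state_min`, `state_max`, `status`.
#' @export
build_character_matrix <- function(maps, policy = c("missing", "optimistic", "pessimistic"),
                                   contains = character()) {
  policy <- match.arg(policy)
  if (length(maps) < 2) abort("need at least two maps")
  taxa <- vapply(maps, function(m) m$taxon, character(1))
  if (is.null(names(maps))) names(maps) <- taxa
  if (anyDuplicated(taxa)) abort("taxon name collision across maps")

  occ <- purrr::map(maps, extract_associations)
  assoc_ids <- sort(unique(unlist(purrr::map(occ, "association"))))

  assoc_rows <- purrr::map(taxa, function(t) {
    o <- occ[[t]]
    failed <- maps[[t]]$probes_failed
    purrr::map(assoc_ids, function(a) {
      mem <- association_members(a)
      hits <- if (a %in% contains) {
        purrr::map_lgl(o$association, function(x) all(mem %in% association_members(x)))
      } else {
        o$association == a
      }
      n_cert <- sum(hits & !o$uncertain)
      n_max <- sum(hits)
      probe_gap <- n_max == 0 && any(mem %in% failed)
      st <- switch(policy,
        optimistic = list(min = n_max, max = n_max,
                          status = if (probe_gap) "missing" else "observed"),
        pessimistic = list(min = n_cert, max = n_cert,
                           status = if (probe_gap) "missing" else "observed"),
        missing = {
          if (probe_gap || (n_cert == 0 && n_max > 0)) {
            list(min = NA_integer_, max = NA_integer_, status = "missing")
          } else if (n_cert == n_max) {
            list(min = n_cert, max = n_max, status = "observed")
          } else {
            list(min = n_cert, max = n_max, status = "range")
          }
        })
      tibble(taxon = t, character = a, kind = "association",
             state_min = as.integer(st$min), state_max = as.integer(st$max),
             status = st$status)
    }) |> bind_rows()
  }) |> bind_rows()

  count_rows <- purrr::map(taxa, function(t) {
    fc <- extract_fragment_counts(maps[[t]])
    fc |>
      mutate(
        taxon = t, character = paste0("HSA", .data$hsa), kind = "fragment_count",
        state_min = dplyr::case_when(
          .data$status == "missing" ~ NA_integer_,
          policy == "optimistic" ~ .data$count_max,
          TRUE ~ .data$count_min),
        state_max = dplyr::case_when(
          .data$status == "missing" ~ NA_integer_,
          policy == "pessimistic" ~ .data$count_min,
          TRUE ~ .data$count_max),
        status = if_else(.data$status == "range" & policy != "missing",
                         "observed", .data$status)
      ) |>
      select("taxon", "character", "kind", "state_min", "state_max", "status")
  }) |> bind_rows()

  out <- bind_rows(assoc_rows, count_rows) |>
    arrange(.data$kind, .data$character, match(.data$taxon, taxa))
  as_character_matrix(out, policy)
}

#' Character states as a named vector, for one character
#'
#' @param matrix A `karyo_matrix`.
#' @param character Character identity (e.g. `"7/10"` or `"HSA8"`).
#' @return Tibble with `taxon`, `state_min`, `state_max`, `status`.
#' @export
character_states <- function(matrix, character) {
  rows <- matrix[matrix$character == character, , drop = FALSE]
  if (nrow(rows) == 0) abort(paste0("unknown character: ", character))
  as_tibble(rows)[, c("taxon", "state_min", "state_max", "status")]
}

#' @export
autoplot.karyo_matrix <- function(object, ...) {
  dat <- as_tibble(object) |>
    mutate(label = dplyr::case_when(
      .data$status == "missing" ~ "?",
      .data$state_min == .data$state_max ~ as.character(.data$state_min),
      TRUE ~ paste0(.data$state_min, "-", .data$state_max)
    ))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$character, y = .data$taxon)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$label), colour = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.5) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$kind),
                        scales = "free_x", space = "free_x") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = NULL)
}
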