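# A painting map is one species' karyotype as seen through Zoo-FISH with
# human whole-chromosome probes: each chromosome pair carries an ordered (or
# order-unknown) list of human-chromosome blocks, plus pairs no probe painted.
# All counts are per haploid complement except the diploid number.

#' Construct a painting map
#'
#' @param segments Tibble with one row per conserved segment: columns
#'   `chrom_id`, `hsa`, and optionally `arm_hint`, `sub_block`, `uncertain`,
#'   `seg` (order along the chromosome).
#' @param chromosomes Tibble with one row per chromosome pair: `chrom_id` and
#'   optional logical columns `is_sex`, `unpainted`, `unordered`,
#'   `uncertain_chrom` and integer columns `unpainted_regions` (euchromatic
#'   regions labeled by no probe), `het_regions` (C-band-positive regions,
#'   recorded but excluded from all counts). Chromosomes absent from
#'   `segments` must be flagged `unpainted`.
#' @param taxon Short taxon code (e.g. `"BTO"`).
#' @param species Full species name.
#' @param diploid_number_reported Published 2n, if any.
#' @param sex_chromosome_count Number of sex chromosomes in the complement
#'   (2 for XY/XX; 1 where an unpaired X remains after a Y/autosome
#'   translocation).
#' @param probes_failed Human chromosomes with no hybridization data.
#' @param notes Free-text provenance notes.
#' @return An object of class `painting_map`.
#' @export
painting_map <- function(segments, chromosomes = NULL, taxon,
                         species = taxon, diploid_number_reported = NA_integer_,
                         sex_chromosome_count = 2L,
                         probes_failed = character(), notes = character()) {
  segments <- as_tibble(segments)
  for (col in c("arm_hint", "sub_block")) {
    if (!col %in% names(segments)) segments[[col]] <- NA_character_
  }
  if (!"uncertain" %in% names(segments)) segments$uncertain <- FALSE
  if (!"seg" %in% names(segments)) {
    segments <- segments |>
      group_by(.data$chrom_id) |>
      mutate(seg = row_number()) |>
      ungroup()
  }
  if (is.null(chromosomes)) {
    chromosomes <- tibble(chrom_id = unique(segments$chrom_id))
  }
  chromosomes <- as_tibble(chromosomes)
  for (col in c("is_sex", "unpainted", "unordered", "uncertain_chrom")) {
    if (!col %in% names(chromosomes)) chromosomes[[col]] <- FALSE
    chromosomes[[col]][is.na(chromosomes[[col]])] <- FALSE
  }
  for (col in c("unpainted_regions", "het_regions")) {
    if (!col %in% names(chromosomes)) chromosomes[[col]] <- 0L
    chromosomes[[col]][is.na(chromosomes[[col]])] <- 0L
  }
  bad <- setdiff(segments$hsa, HSA_LEVELS)
  if (length(bad) > 0) {
    abort(paste0("unknown human chromosome label(s): ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(chromosomes$chrom_id)) {
    abort("duplicate chrom_id in chromosome table")
  }
  orphan <- setdiff(segments$chrom_id, chromosomes$chrom_id)
  if (length(orphan) > 0) {
    abort(paste0("segments reference unknown chromosome(s): ",
                 paste(orphan, collapse = ", ")))
  }
  structure(
    list(
      taxon = taxon, species = species,
      diploid_number_reported = as.integer(diploid_number_reported),
      sex_chromosome_count = as.integer(sex_chromosome_count),
      probes_failed = probes_failed,
      chromosomes = chromosomes, segments = segments, notes = notes
    ),
    class = "painting_map"
  )
}

#' @export
print.painting_map <- function(x, ...) {
  cat("<painting_map> ", x$taxon, " (", x$species, ")\n", sep = "")
  cat("  reported 2n: ", x$diploid_number_reported,
      "; chromosome pairs: ", nrow(x$chromosomes),
      " (", sum(x$chromosomes$unpainted), " unpainted)\n", sep = "")
  cat("  segments: ", count_segments(x), " certain",
      if (any(x$segments$uncertain)) paste0(" + ", sum(x$segments$uncertain), " uncertain"),
      "; junctions: ", count_junctions(x), "\n", sep = "")
  if (length(x$probes_failed) > 0) {
    cat("  probes without data: HSA ", paste(x$probes_failed, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.painting_map <- function(x, ...) {
  x$segments |>
    mutate(taxon = x$taxon, .before = 1) |>
    left_join(x$chromosomes, by = "chrom_id")
}

#' @export
glance.painting_map <- function(x, ...) {
  tibble(
    taxon = x$taxon,
    n_chromosome_pairs = nrow(x$chromosomes),
    n_segments = count_segments(x),
    n_junctions = count_junctions(x),
    diploid_number = diploid_number(x),
    diploid_number_reported = x$diploid_number_reported
  )
}

#' @export
autoplot.painting_map <- function(object, ...) {
  dat <- tidy(object) |>
    mutate(label = format_block_label(.data$hsa, .data$arm_hint,
                                      .data$sub_block, .data$uncertain))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$chrom_id, y = .data$seg)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$hsa), colour = "grey20",
                       width = 0.7, height = 0.95) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = "segment",
                  title = paste0(object$species, " (2n = ",
                                 object$diploid_number_reported, ")"))
}

segment_rows <- function(map, uncertain = c("exclude", "include")) {
  uncertain <- match.arg(uncertain)
  seg <- filter(map$segments, .data$hsa != "Y")
  if (uncertain == "exclude") {
    chr <- map$chromosomes
    unc_chr <- chr$chrom_id[chr$uncertain_chrom]
    seg <- filter(seg, !.data$uncertain, !(.data$chrom_id %in% unc_chr))
  }
  seg
}

#' Count conserved segments
#'
#' Total number of human-chromosome blocks across a painting map, X included,
#' Y and unpainted regions excluded. Segments flagged uncertain ("?") are
#' excluded by default.
#'
#' @param map A [painting_map()].
#' @param uncertain `"exclude"` (default) or `"include"` uncertain segments.
#' @return Integer segment count.
#' @export
count_segments <- function(map, uncertain = c("exclude", "include")) {
  nrow(segment_rows(map, uncertain))
}

#' Count segment junctions
#'
#' Sum over chromosomes of (number of segments - 1): the block-to-block
#' contacts that witness ancestral or derived fusions. Uses the same
#' uncertainty handling as [count_segments()], so that for any map
#' `painted chromosomes = count_segments - count_junctions` exactly.
#'
#' @inheritParams count_segments
#' @return Integer junction count.
#' @export
count_junctions <- function(map, uncertain = c("exclude", "include")) {
  seg <- segment_rows(map, uncertain)
  if (nrow(seg) == 0) return(0L)
  sum(pmax(table(seg$chrom_id) - 1L, 0L))
}

#' Diploid number of a painting map
#'
#' `2 * (painted + unpainted autosome pairs) + sex chromosome count`.
#' Chromosomes flagged uncertain still count as pairs (the pair exists; what
#' paints it is uncertain).
#'
#' @param map A [painting_map()].
#' @return Integer 2n.
#' @export
diploid_number <- function(map) {
  aut <- sum(!map$chromosomes$is_sex)
  2L * aut + map$sex_chromosome_count
}

#' Validate a painting map
#'
#' Checks the structural invariants and returns a tibble of violations
#' (empty when the map is clean). `severity` is `"error"` for structural
#' breaks and `"advisory"` for tensions the printed source data cannot
#' resolve (e.g. a reported 2n the transcribed inventory does not reach).
#'
#' @param map A [painting_map()].
#' @return Tibble with columns `chrom_id`, `rule`, `severity`, `message`.
#' @export
validate_map <- function(map) {
  out <- list()
  note <- function(chrom_id, rule, severity, message) {
    out[[length(out) + 1]] <<- tibble(
      chrom_id = chrom_id, rule = rule, severity = severity, message = message
    )
  }
  chr <- map$chromosomes
  seg <- map$segments

  # painted chromosomes must have segments; unpainted must not
  painted_ids <- unique(seg$chrom_id)
  for (id in chr$chrom_id[!chr$unpainted & !(chr$chrom_id %in% painted_ids)]) {
    note(id, "empty_chromosome", "error",
         "chromosome has no segments and is not flagged unpainted")
  }
  for (id in intersect(chr$chrom_id[chr$unpainted], painted_ids)) {
    note(id, "unpainted_with_segments", "error",
         "chromosome flagged unpainted but carries segments")
  }

  # >=2 blocks of one human chromosome need distinct sub-block tags
  dup <- seg |>
    mutate(tag = paste0(ifelse(is.na(.data$arm_hint), "", .data$arm_hint),
                        ifelse(is.na(.data$sub_block), "", .data$sub_block))) |>
    group_by(.data$hsa) |>
    filter(n() > 1) |>
    filter(anyDuplicated(.data$tag) > 0) |>
    ungroup()
  for (h in unique(dup$hsa)) {
    note(NA_character_, "ambiguous_sub_blocks", "error",
         paste0("HSA ", h, " has multiple blocks without distinct sub-block tags"))
  }

  # every human chromosome accounted for: painted, failed probe, or flagged
  seen <- union(unique(seg$hsa), map$probes_failed)
  missing_hsa <- setdiff(setdiff(HSA_LEVELS, "Y"), seen)
  for (h in missing_hsa) {
    note(NA_character_, "hsa_unaccounted", "advisory",
         paste0("HSA ", h, " in neither segments nor probes_failed"))
  }

  # reported 2n vs structure
  if (!is.na(map$diploid_number_reported) &&
      diploid_number(map) != map$diploid_number_reported) {
    note(NA_character_, "diploid_mismatch", "advisory",
         paste0("structural 2n = ", diploid_number(map),
                " but reported 2n = ", map$diploid_number_reported,
                " (transcribed inventory incomplete)"))
  }
  if (length(out) == 0) {
    return(tibble(chrom_id = character(), rule = character(),
                  severity = character(), message = character()))
  }
  bind_rows(out)
}
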