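# Ancestral karyotype assembly: inferred per-human-chromosome block counts
# plus inferred associations (with explicit sub-block assignments) define a
# block-adjacency graph whose connected components are the ancestral
# chromosomes. Linear chromosomes require every block to sit in at most one
# association path, and every adjacency to reference an existing block.

#' Assemble a karyotype from blocks and adjacencies
#'
#' @param blocks Tibble with columns `hsa`, `count` (blocks per human
#'   chromosome; chromosomes with count 0 are dropped).
#' @param adjacencies Tibble with columns `character` (association identity,
#'   e.g. `"3/21"`), `occurrence` (1, 2, ... for repeated associations),
#'   `hsa`, `block_index` (which block of that human chromosome joins this
#'   association). All members of one association occurrence are joined into
#'   one chromosome.
#' @param sex_chromosome_count Sex chromosomes added to the diploid number
#'   (default 2; the X is always its own component).
#' @param provenance Optional tibble carried through to the result.
#' @return An `ancestral_karyotype`: blocks, adjacency edges, chromosomes
#'   (lists of block ids), diploid number, conflicts (empty on success).
#' @examples
#' blocks <- tibble::tibble(hsa = c("3", "21", "5"), count = 1L)
#' adj <- tibble::tibble(character = "3/21", occurrence = 1L,
#'                       hsa = c("3", "21"), block_index = 1L)
#' assemble_karyotype(blocks, adj)
#' @export
assemble_karyotype <- function(blocks, adjacencies = NULL,
                               sex_chromosome_count = 2L, provenance = NULL) {
  blocks <- as_tibble(blocks) |> filter(.data$count > 0)
  block_ids <- purrr::pmap(blocks, function(hsa, count, ...) {
    if (count == 1) hsa else paste0(hsa, letters[seq_len(count)])
  }) |> unlist()
  id_of <- function(hsa, idx) {
    n <- blocks$count[blocks$hsa == hsa]
    if (length(n) == 0 || is.na(idx) || idx > n) return(NA_character_)
    if (n == 1) hsa else paste0(hsa, letters[idx])
  }

  conflicts <- character(0)
  edges <- tibble(from = character(), to = character(), character = character(),
                  occurrence = integer())
  if (!is.null(adjacencies) && nrow(adjacencies) > 0) {
    adj <- as_tibble(adjacencies) |>
      mutate(block_id = purrr::map2_chr(.data$hsa, .data$block_index, id_of))
    bad <- adj |> filter(is.na(.data$block_id))
    for (i in seq_len(nrow(bad))) {
      conflicts <- c(conflicts, paste0(
        "adjacency ", bad$character[i], " references HSA ", bad$hsa[i],
        " block ", bad$block_index[i], ", which the inferred counts do not provide"))
    }
    adj <- filter(adj, !is.na(.data$block_id))
    edges <- adj |>
      group_by(.data$character, .data$occurrence) |>
      dplyr::reframe(from = head(.data$block_id, -1), to = tail(.data$block_id, -1))
  }

  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = block_ids)
  )
  deg <- igraph::degree(g)
  for (b in names(deg)[deg > 2]) {
    conflicts <- c(conflicts, paste0(
      "block ", b, " has ", deg[b], " adjacency endpoints; chromosomes are linear"))
  }
  comp <- igraph::components(g)
  chroms <- split(names(comp$membership), comp$membership)
  # deterministic canonical naming: order components by their smallest block
  key <- vapply(chroms, function(x) {
    x <- x[order(hsa_rank(sub("[a-f]$", "", x)), x)]
    paste(x, collapse = "/")
  }, character(1))
  ord <- order(hsa_rank(sub("[a-f/].*$", "", key)), key)
  chroms <- purrr::map(chroms[ord], function(x) x[order(hsa_rank(sub("[a-f]$", "", x)), x)])
  names(chroms) <- paste0("anc_", sprintf("%02d", seq_along(chroms)))

  autosomal <- vapply(chroms, function(x) !any(sub("[a-f]$", "", x) == "X"), logical(1))
  structure(
    list(
      blocks = blocks,
      adjacencies = edges,
      chromosomes = chroms,
      diploid_number = 2L * sum(autosomal) + as.integer(sex_chromosome_count),
      sex_chromosome_count = as.integer(sex_chromosome_count),
      conflicts = conflicts,
      provenance = provenance
    ),
    class = "ancestral_karyotype"
  )
}

#' @export
print.ancestral_karyotype <- function(x, ...) {
  cat("<ancestral_karyotype> 2n = ", x$diploid_number, " (",
      length(x$chromosomes), " chromosome pairs incl. sex pair)\n", sep = "")
  fused <- x$chromosomes[vapply(x$chromosomes, length, integer(1)) > 1]
  if (length(fused) > 0) {
    cat("  fused chromosomes:",
        paste(vapply(fused, paste, character(1), collapse = "/"), collapse = "; "), "\n")
  }
  if (length(x$conflicts) > 0) {
    cat("  CONFLICTS:\n"); for (cf in x$conflicts) cat("   -", cf, "\n")
  }
  invisible(x)
}

#' @export
tidy.ancestral_karyotype <- function(x, ...) {
  purrr::imap(x$chromosomes, function(blocks, id) {
    tibble(chromosome = id, block = blocks,
           hsa = sub("[a-f]$", "", blocks), n_blocks = length(blocks))
  }) |> bind_rows()
}

#' @export
glance.ancestral_karyotype <- function(x, ...) {
  tibble(
    diploid_number = x$diploid_number,
    n_chromosomes = length(x$chromosomes),
    n_blocks = sum(x$blocks$count),
    n_adjacencies = nrow(x$adjacencies),
    n_conflicts = length(x$conflicts)
  )
}

#' Association identities present in an assembled karyotype
#'
#' @param karyotype An `ancestral_karyotype`.
#' @return Tibble `association`, `multiplicity`.
#' @export
karyotype_associations <- function(karyotype) {
  multi <- purrr::keep(karyotype$chromosomes, function(x) {
    length(unique(sub("[a-f]$", "", x))) >= 2
  })
  if (length(multi) == 0) {
    return(tibble(association = character(), multiplicity = integer()))
  }
  tibble(association = unname(vapply(multi, function(x) {
    association_id(unique(sub("[a-f]$", "", x)))
  }, character(1)))) |>
    count(.data$association, name = "multiplicity") |>
    arrange(.data$association)
}

#' Compare two karyotypes
#'
#' Symmetric difference of association content and per-chromosome block
#' counts, plus the diploid-number delta.
#'
#' @param a,b `ancestral_karyotype` objects.
#' @return List with `associations` (tibble: association, in_a, in_b),
#'   `fragment_counts` (tibble: hsa, count_a, count_b), `diploid_delta`.
#' @export
compare_karyotypes <- function(a, b) {
  aa <- karyotype_associations(a); ab <- karyotype_associations(b)
  assoc <- dplyr::full_join(aa, ab, by = "association",
                            suffix = c("_a", "_b")) |>
    mutate(across(dplyr::starts_with("multiplicity"), ~tidyr::replace_na(.x, 0L))) |>
    filter(.data$multiplicity_a != .data$multiplicity_b)
  counts <- dplyr::full_join(
    rename(a$blocks, count_a = "count"),
    rename(b$blocks, count_b = "count"), by = "hsa") |>
    mutate(across(dplyr::starts_with("count"), ~tidyr::replace_na(.x, 0L))) |>
    filter(.data$count_a != .data$count_b)
  list(
    associations = assoc,
    fragment_counts = counts,
    diploid_delta = a$diploid_number - b$diploid_number
  )
}

#' @export
autoplot.ancestral_karyotype <- function(object, ...) {
  dat <- tidy(object) |>
    group_by(.data$chromosome) |>
    mutate(pos = row_number()) |>
    ungroup()
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$chromosome, y = .data$pos)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$hsa), colour = "grey20",
                       width = 0.7, height = 0.95) +
    ggplot2::geom_text(ggplot2::aes(label = .data$block), size = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = "block position",
                  title = paste0("Ancestral karyotype, 2n = ", object$diploid_number))
}
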