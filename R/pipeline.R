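# Config-driven end-to-end run: read maps and tree, build the character
# matrix, reconstruct every character, infer the ancestral karyotype at the
# target node, detect clade signatures, and write a report bundle (TSV +
# NEXUS matrix, reconstruction provenance, karyotype JSON, signature tables,
# and a summary table mirroring the published correspondence-table layout).
# Two runs from the same config and fixtures produce identical bundles.

#' Summary table of painting maps
#'
#' One row per taxon in the layout of published human-probe correspondence
#' tables: associations (with multiplicities and "?" marks), conserved
#' (single-block) human chromosomes, two-block and three-or-more-block
#' chromosomes.
#'
#' @param maps Named list of [painting_map()] objects.
#' @return Tibble with columns `taxon`, `diploid_number`, `associations`,
#'   `conserved`, `two_blocks`, `three_plus`.
#' @export
table1_summary <- function(maps) {
  purrr::map(maps, function(m) {
    occ <- extract_associations(m)
    assoc <- occ |>
      group_by(.data$association) |>
      summarise(n = n(), unc = all(.data$uncertain)) |>
      mutate(txt = paste0(.data$association,
                          if_else(.data$n > 1, paste0("(", .data$n, "x)"), ""),
                          if_else(.data$unc, "?", ""))) |>
      arrange(hsa_rank(sub("/.*$", "", .data$association)), .data$association)
    fc <- extract_fragment_counts(m) |>
      mutate(txt = paste0(.data$hsa, if_else(.data$status == "range", "?", ""))) |>
      arrange(hsa_rank(.data$hsa))
    col <- function(lo, hi) {
      rows <- fc[fc$status != "missing" &
                   pmax(fc$count_min, fc$count_max) >= lo &
                   pmax(fc$count_min, fc$count_max) <= hi, ]
      paste(rows$txt, collapse = ", ")
    }
    tibble(
      taxon = m$taxon, diploid_number = m$diploid_number_reported,
      associations = paste(assoc$txt, collapse = ", "),
      conserved = col(1, 1), two_blocks = col(2, 2), three_plus = col(3, 99)
    )
  }) |> bind_rows()
}

load_maps_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  if (length(files) == 0) {
    abort(paste0("pipeline stage 'load_maps': no painting-map TSV files in ", dir))
  }
  maps <- lapply(sort(files), read_painting_map)
  setNames(maps, vapply(maps, function(m) m$taxon, character(1)))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "': ", conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' @param config A named list, or a path to a YAML file with the same
#'   fields. Recognized fields: `maps_dir` (directory of painting-map TSVs;
#'   default: the packaged maps), `tree` (Newick path; default: packaged
#'   tree), `node` (target ancestor, default `"Xenarthra"`),
#'   `exclude_taxa` (default `"AEKALT"`), `signature_clades` (default
#'   Xenarthra, Bradypus, BradypusCrown, Pilosa, Folivora), `out_dir`
#'   (required), plus any analysis fields of [study_config()].
#' @return Invisibly, a list with the matrix, reconstructions, karyotype,
#'   signatures and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  run <- config_defaults(config)
  if (is.null(run$out_dir)) abort("config needs an out_dir")
  out <- run$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  node <- run$node %||% "Xenarthra"
  clades <- run$signature_clades %||%
    c("Xenarthra", "Bradypus", "BradypusCrown", "Pilosa", "Folivora")

  maps <- stage("load_maps", {
    if (!is.null(run$maps_dir)) load_maps_dir(run$maps_dir) else xen_painting_maps()
  })
  maps <- maps[setdiff(names(maps), run$exclude_taxa %||% "AEKALT")]
  tree <- stage("load_tree", {
    if (!is.null(run$tree)) read_tree(run$tree) else xen_tree()
  })

  matrix <- stage("character_matrix",
                  build_character_matrix(maps, policy = run$policy,
                                         contains = run$contains))
  write_character_matrix(matrix, file.path(out, "matrix.tsv"), "tsv")
  write_character_matrix(matrix, file.path(out, "matrix.nex"), "nexus")

  karyotype <- stage("infer_karyotype",
                     infer_ancestral_karyotype(maps, tree, node, run))

  recon_json <- karyotype$provenance |>
    mutate(node = node, .before = 1)
  jsonlite::write_json(recon_json, file.path(out, "reconstructions.json"),
                       dataframe = "rows", pretty = TRUE)

  jsonlite::write_json(
    list(
      node = node,
      diploid_number = karyotype$diploid_number,
      chromosomes = karyotype$chromosomes,
      associations = karyotype_associations(karyotype),
      blocks = karyotype$blocks,
      conflicts = karyotype$conflicts,
      variants = dplyr::mutate(karyotype$variants,
                               alternatives = purrr::map_chr(.data$alternatives,
                                                             paste, collapse = "|"))
    ),
    file.path(out, "karyotype.json"), dataframe = "rows", pretty = TRUE,
    auto_unbox = TRUE
  )

  signatures <- stage("signatures", {
    purrr::map(setNames(clades, clades), function(cl) {
      clade_signatures(maps, tree, cl, run)
    })
  })
  sig_tab <- purrr::imap(signatures, function(s, cl) {
    if (nrow(s) == 0) return(NULL)
    mutate(s, clade = cl, .before = 1)
  }) |> purrr::compact() |> bind_rows()
  jsonlite::write_json(signatures, file.path(out, "signatures.json"),
                       dataframe = "rows", pretty = TRUE)
  readr::write_tsv(sig_tab, file.path(out, "signatures.tsv"))

  readr::write_tsv(table1_summary(maps), file.path(out, "summary.tsv"))

  # audit trail: every tie-break, override and assertion that shaped the result
  audit <- karyotype$provenance |>
    filter(.data$resolved_by != "unambiguous")
  readr::write_tsv(audit, file.path(out, "audit.tsv"))

  if (length(karyotype$conflicts) > 0) {
    warn(paste0("assembly conflicts: ",
                paste(karyotype$conflicts, collapse = "; ")))
  }
  invisible(list(
    matrix = matrix, karyotype = karyotype, signatures = signatures,
    summary = table1_summary(maps), out_dir = out,
    ok = length(karyotype$conflicts) == 0
  ))
}
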