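# Painting-map files are TSV with a '#key<TAB>value' metadata header and one
# row per chromosome pair:
#
#   #taxon	BTO
#   #species	Bradypus torquatus
#   #diploid_number_reported	50
#   chrom_id	segments	flags
#   BTO_01	3,21
#   BTO_23		unpainted
#   BTO_X	X	sex
#
# 'segments' is a comma-separated list of block labels in order along the
# chromosome ("8a", "16q", "21?"); 'flags' is a comma-separated list among
# sex, unpainted, unordered, uncertain, unpainted_regions:<n>, het_regions:<n>.

#' Read a painting map from TSV
#'
#' @param path File path.
#' @return A [painting_map()].
#' @export
read_painting_map <- function(path) {
  lines <- readr::read_lines(path)
  meta_lines <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  meta <- list()
  for (ln in meta_lines) {
    kv <- stringr::str_split_1(sub("^#", "", ln), "\t")
    if (length(kv) >= 2) meta[[kv[1]]] <- kv[2]
  }
  if (length(body) < 1) abort(paste0(path, ": no chromosome records"))
  tab <- readr::read_tsv(I(body), col_types = "ccc",
                         col_names = c("chrom_id", "segments", "flags"),
                         skip = 1, na = character())
  header <- stringr::str_split_1(body[1], "\t")
  if (!identical(header[1:2], c("chrom_id", "segments"))) {
    abort(paste0(path, ": expected header 'chrom_id\tsegments\tflags'"))
  }
  if (anyDuplicated(tab$chrom_id)) {
    abort(paste0(path, ": duplicate chrom_id: ",
                 tab$chrom_id[duplicated(tab$chrom_id)][1]))
  }

  parse_flags <- function(flags) {
    toks <- if (!nzchar(flags)) character() else stringr::str_split_1(flags, ",")
    toks <- trimws(toks)
    known <- c("sex", "unpainted", "unordered", "uncertain")
    counted <- stringr::str_match(toks, "^(unpainted_regions|het_regions):(\\d+)$")
    plain <- toks[is.na(counted[, 1])]
    bad <- setdiff(plain, known)
    if (length(bad) > 0) abort(paste0("unknown flag(s): ", paste(bad, collapse = ", ")))
    res <- list(is_sex = "sex" %in% plain, unpainted = "unpainted" %in% plain,
                unordered = "unordered" %in% plain,
                uncertain_chrom = "uncertain" %in% plain,
                unpainted_regions = 0L, het_regions = 0L)
    for (i in which(!is.na(counted[, 1]))) {
      res[[counted[i, 2]]] <- as.integer(counted[i, 3])
    }
    res
  }

  chrom_rows <- purrr::map2(tab$chrom_id, tab$flags, function(id, fl) {
    c(list(chrom_id = id), parse_flags(fl))
  })
  chromosomes <- bind_rows(chrom_rows)

  seg_rows <- purrr::map2(tab$chrom_id, tab$segments, function(id, s) {
    if (!nzchar(s)) return(NULL)
    toks <- trimws(stringr::str_split_1(s, ","))
    if (any(!nzchar(toks))) abort(paste0(path, ": empty segment token on ", id))
    parsed <- parse_block_label(toks)
    parsed$chrom_id <- id
    parsed$seg <- seq_len(nrow(parsed))
    parsed
  })
  segments <- bind_rows(seg_rows)
  seg_ids <- if (nrow(segments) > 0) segments$chrom_id else character()
  empty_painted <- chromosomes$chrom_id[!chromosomes$unpainted &
                                          !(chromosomes$chrom_id %in% seg_ids)]
  if (length(empty_painted) > 0) {
    abort(paste0(path, ": chromosome record without segments: ",
                 paste(empty_painted, collapse = ", "),
                 " (flag 'unpainted' if intended)"))
  }

  probes_failed <- if (is.null(meta$probes_failed) || !nzchar(meta$probes_failed)) {
    character()
  } else {
    trimws(stringr::str_split_1(meta$probes_failed, ","))
  }
  painting_map(
    segments = segments, chromosomes = chromosomes,
    taxon = meta$taxon %||% tools::file_path_sans_ext(basename(path)),
    species = meta$species %||% meta$taxon %||% basename(path),
    diploid_number_reported = as.integer(meta$diploid_number_reported %||% NA),
    sex_chromosome_count = as.integer(meta$sex_chromosome_count %||% 2L),
    probes_failed = probes_failed,
    notes = meta$note %||% character()
  )
}

#' Write a painting map to TSV
#'
#' Round-trips with [read_painting_map()].
#'
#' @param map A [painting_map()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_painting_map <- function(map, path) {
  meta <- c(
    paste0("#taxon\t", map$taxon),
    paste0("#species\t", map$species),
    if (!is.na(map$diploid_number_reported))
      paste0("#diploid_number_reported\t", map$diploid_number_reported),
    paste0("#sex_chromosome_count\t", map$sex_chromosome_count),
    if (length(map$probes_failed) > 0)
      paste0("#probes_failed\t", paste(map$probes_failed, collapse = ",")),
    if (length(map$notes) > 0) paste0("#note\t", map$notes[1])
  )
  seg_str <- map$segments |>
    arrange(.data$chrom_id, .data$seg) |>
    group_by(.data$chrom_id) |>
    summarise(segments = paste(
      format_block_label(.data$hsa, .data$arm_hint, .data$sub_block, .data$uncertain),
      collapse = ","))
  rows <- map$chromosomes |>
    left_join(seg_str, by = "chrom_id") |>
    mutate(segments = if_else(is.na(.data$segments), "", .data$segments)) |>
    mutate(flags = purrr::pmap_chr(
      list(.data$is_sex, .data$unpainted, .data$unordered, .data$uncertain_chrom,
           .data$unpainted_regions, .data$het_regions),
      function(sx, up, uo, uc, ur, hr) {
        paste(c(if (sx) "sex", if (up) "unpainted", if (uo) "unordered",
                if (uc) "uncertain",
                if (ur > 0) paste0("unpainted_regions:", ur),
                if (hr > 0) paste0("het_regions:", hr)), collapse = ",")
      }))
  body <- c("chrom_id\tsegments\tflags",
            paste(rows$chrom_id, rows$segments, rows$flags, sep = "\t"))
  readr::write_lines(c(meta, body), path)
  invisible(path)
}

#' Read a rooted tree with named internal nodes
#'
#' Thin wrapper over [ape::read.tree()] that insists on a rooted topology.
#' Polytomies are allowed and recorded.
#'
#' @param source Newick string or file path.
#' @return An `ape` `phylo` object.
#' @export
read_tree <- function(source) {
  phy <- if (file.exists(source)) ape::read.tree(source) else ape::read.tree(text = source)
  if (is.null(phy)) abort("could not parse Newick input")
  # a basal trifurcation is the Newick convention for an unrooted tree;
  # polytomies at internal (non-root) nodes remain allowed
  if (length(phy$tip.label) > 2 && !ape::is.rooted(phy)) {
    abort("tree must be rooted (root it on an outgroup first)")
  }
  phy
}

#' Write a character matrix
#'
#' `tsv` writes the long tidy form and round-trips losslessly via
#' [read_character_matrix()]. `nexus` writes a standard `DATA` block with
#' symbols `0-9` and `?` for missing, loadable by standard phylogenetics
#' software; integer ranges collapse to `?` in that dialect.
#'
#' @param matrix A character matrix from [build_character_matrix()].
#' @param path Output path.
#' @param dialect `"tsv"` or `"nexus"`.
#' @return `path`, invisibly.
#' @export
write_character_matrix <- function(matrix, path, dialect = c("tsv", "nexus")) {
  dialect <- match.arg(dialect)
  chars <- attr(matrix, "characters")
  if (anyDuplicated(chars$character)) {
    abort("character names collide after canonicalization")
  }
  if (dialect == "tsv") {
    hdr <- paste0("#uncertainty_policy\t", attr(matrix, "uncertainty_policy"))
    readr::write_lines(hdr, path)
    readr::write_tsv(matrix, path, append = TRUE, col_names = TRUE)
    return(invisible(path))
  }
  taxa <- attr(matrix, "taxa")
  # ranges collapse to "?" in this interchange dialect (the TSV dialect
  # round-trips them losslessly)
  wide <- matrix |>
    mutate(sym = dplyr::case_when(
      .data$status == "missing" ~ "?",
      .data$state_min == .data$state_max ~ as.character(.data$state_min),
      TRUE ~ "?"
    )) |>
    select("taxon", "character", "sym") |>
    tidyr::pivot_wider(names_from = "character", values_from = "sym")
  wide <- wide[match(taxa, wide$taxon), ]
  rowstr <- apply(as.matrix(wide[, -1, drop = FALSE]), 1, paste, collapse = "")
  lines <- c(
    "#NEXUS",
    "BEGIN DATA;",
    paste0("  DIMENSIONS NTAX=", length(taxa), " NCHAR=", nrow(chars), ";"),
    "  FORMAT DATATYPE=STANDARD SYMBOLS=\"0123456789\" MISSING=? GAP=- INTERLEAVE=NO;",
    "  CHARLABELS",
    paste0("    '", gsub("/", "_", chars$character), "'"),
    "  ;",
    "  MATRIX",
    paste0("    ", format(wide$taxon, width = max(nchar(taxa)) + 2), rowstr),
    "  ;",
    "END;"
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a TSV character matrix written by [write_character_matrix()]
#'
#' @param path File path.
#' @return A character matrix (long tibble) with the same attributes.
#' @export
read_character_matrix <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  policy <- sub("^#uncertainty_policy\t", "", first)
  tab <- readr::read_tsv(path, comment = "#", col_types = "ccciic")
  attr(tab, "spec") <- NULL
  attr(tab, "problems") <- NULL
  as_character_matrix(tab, policy = policy)
}
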