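# Character-history classification and clade-signature detection. A
# chromosome signature (synapomorphy) of a clade is a derived state gained
# on the clade's stem branch and absent outside the clade among scored taxa;
# count characters qualify through a stem-branch count change (e.g. a
# 2 -> 3 block fission). Signatures are reported with caveats when an
# in-clade taxon lacks the state or could not be scored.

#' Classify a character's history
#'
#' Classifies each enumerated most parsimonious reconstruction and reports
#' the class when all MPRs agree:
#'
#' * `symplesiomorphy` -- the derived state is already present at the root
#'   (ancestral presence; losses and regains are noted), or the character
#'   does not vary;
#' * `synapomorphy` -- a single gain on an internal stem branch (losses
#'   nested inside the clade become caveats);
#' * `autapomorphy` -- a single gain on a terminal branch;
#' * `homoplasy` -- two or more independent gains;
#' * `ambiguous` -- MPRs disagree on the class.
#'
#' @param rec A binary `karyo_reconstruction` (Fitch or Dollo).
#' @param tree The tree it was computed on.
#' @return One-row tibble: `character`, `classification`, `clade`,
#'   `n_mprs`, `detail`.
#' @export
classify_character <- function(rec, tree) {
  if (!rec$engine %in% c("fitch", "dollo")) {
    abort("classify_character expects a binary (Fitch/Dollo) reconstruction")
  }
  if (length(rec$mprs) == 0) {
    abort("no enumerated MPRs (tree too large?); classification unavailable")
  }
  nm <- node_names(tree)
  root_name <- nm[root_of(tree)]
  obs <- rec$tip_states[rec$tip_states$status != "missing" &
                          !is.na(rec$tip_states$state_min), ]
  constant <- length(unique(pmin(obs$state_min, 1))) <= 1

  per_mpr <- purrr::imap(rec$mprs, function(assign, i) {
    ev <- rec$events
    ev <- ev[!is.na(ev$mpr) & ev$mpr == i, , drop = FALSE]
    root_state <- assign[[root_name]]
    gains <- ev[ev$type == "gain", , drop = FALSE]
    losses <- ev[ev$type == "loss", , drop = FALSE]
    if (constant || (nrow(ev) == 0)) {
      tibble(class = "symplesiomorphy", clade = NA_character_,
             detail = "no change")
    } else if (root_state >= 1) {
      tibble(class = "symplesiomorphy",
             clade = NA_character_,
             detail = paste0("ancestral presence; ", nrow(losses), " loss(es)",
                             if (nrow(gains) > 0) paste0(", ", nrow(gains), " regain(s)")))
    } else if (nrow(gains) == 1) {
      child <- gains$child[1]
      is_tip <- child %in% tree$tip.label
      tibble(class = if (is_tip) "autapomorphy" else "synapomorphy",
             clade = child,
             detail = paste0("single gain on ", child, " stem",
                             if (nrow(losses) > 0)
                               paste0("; lost in ", paste(losses$child, collapse = ", "))))
    } else {
      tibble(class = "homoplasy", clade = NA_character_,
             detail = paste0(nrow(gains), " independent gains (",
                             paste(gains$child, collapse = ", "), ")"))
    }
  }) |> bind_rows()

  classes <- unique(per_mpr$class)
  clades <- unique(per_mpr$clade)
  if (length(classes) == 1 && length(clades) == 1) {
    tibble(character = rec$character, classification = classes,
           clade = clades, n_mprs = length(rec$mprs),
           detail = per_mpr$detail[1])
  } else {
    tibble(character = rec$character, classification = "ambiguous",
           clade = NA_character_, n_mprs = length(rec$mprs),
           detail = paste(unique(paste0(per_mpr$class,
                                        ifelse(is.na(per_mpr$clade), "",
                                               paste0("(", per_mpr$clade, ")")))),
                          collapse = " | "))
  }
}

#' Chromosome signatures of a clade
#'
#' Detects characters whose derived state arose on the stem branch of the
#' named clade under the configured resolution policy: association
#' characters through a stem gain, count characters through a stem count
#' change. Missing data never disqualify a signature but are listed, and a
#' signature is caveat-flagged when an in-clade taxon lacks the state.
#'
#' @param maps Named list of [painting_map()] objects (including the
#'   configured outgroup pseudo-taxon).
#' @param tree Rooted `phylo`.
#' @param clade Name of an internal node (or tip, for autapomorphies).
#' @param config See [study_config()].
#' @return Tibble: `character`, `kind`, `change`, `caveat_absent_in`,
#'   `missing_in`; zero rows when the clade has no signature.
#' @export
clade_signatures <- function(maps, tree, clade, config = study_config()) {
  config <- config_defaults(config)
  node_number(tree, clade)  # validates
  matrix <- build_character_matrix(maps, policy = config$policy,
                                   contains = config$contains)
  recs <- reconstruct_characters(matrix, tree, config)
  par <- parent_of(tree)
  nm <- node_names(tree)
  clade_num <- node_number(tree, clade)
  parent_name <- if (is.na(par[clade_num])) NA_character_ else nm[par[clade_num]]
  in_clade <- clade_tip_labels(tree, clade_num)
  scored_taxa <- setdiff(attr(matrix, "taxa"), config$outgroup)

  ov <- config$overrides
  rows <- purrr::imap(recs, function(rec, ch) {
    o <- ov[ov$character == ch, ]
    og_state <- outgroup_state_for(matrix, ch, config$outgroup)
    if (rec$engine != "wagner") og_state <- min(og_state, 1L)
    res <- resolve_ambiguity(
      rec, policy = "outgroup",
      outgroup_state = if (is.na(og_state)) NULL else og_state,
      override = if (nrow(o) > 0 && o$kind[1] == "resolution") o else NULL
    )
    s_clade <- resolved_state(res, clade)
    if (nrow(o) > 0 && o$kind[1] == "assertion" && identical(o$node[1], clade)) {
      s_clade <- o$state[1]
    }
    if (is.na(parent_name)) return(NULL)
    s_parent <- resolved_state(res, parent_name)
    if (s_clade == s_parent) return(NULL)
    st <- rec$tip_states
    if (rec$engine != "wagner") {
      # association: require a stem gain and absence outside the clade
      if (!(s_parent == 0 && s_clade >= 1)) return(NULL)
      outside <- st[st$taxon %in% setdiff(scored_taxa, in_clade), ]
      if (any(outside$state_min >= 1, na.rm = TRUE)) return(NULL)
      absent_in <- st$taxon[st$taxon %in% in_clade & !is.na(st$state_max) &
                              st$state_max == 0 & st$status != "missing"]
      missing_in <- st$taxon[st$taxon %in% in_clade & st$status == "missing"]
      tibble(character = ch, kind = "association",
             change = "gain",
             caveat_absent_in = paste(absent_in, collapse = ","),
             missing_in = paste(missing_in, collapse = ","))
    } else {
      missing_in <- st$taxon[st$taxon %in% in_clade & st$status == "missing"]
      tibble(character = ch, kind = "fragment_count",
             change = paste0(s_parent, "->", s_clade),
             caveat_absent_in = "",
             missing_in = paste(missing_in, collapse = ","))
    }
  })
  rows <- purrr::compact(rows)
  if (length(rows) == 0) {
    return(tibble(character = character(), kind = character(),
                  change = character(), caveat_absent_in = character(),
                  missing_in = character()))
  }
  bind_rows(rows) |> arrange(.data$kind, .data$character)
}

#' Classify every association character of a matrix
#'
#' Convenience wrapper running [classify_character()] across all association
#' characters.
#'
#' @param matrix A `karyo_matrix`.
#' @param tree Rooted `phylo`.
#' @param config See [study_config()].
#' @return Tibble, one row per association character.
#' @export
classify_characters <- function(matrix, tree, config = study_config()) {
  config <- config_defaults(config)
  recs <- reconstruct_characters(matrix, tree, config)
  assoc <- purrr::keep(recs, function(r) r$engine %in% c("fitch", "dollo"))
  purrr::map(assoc, classify_character, tree = tree) |> bind_rows()
}
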