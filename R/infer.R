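# End-to-end ancestral karyotype inference: reconstruct every character at a
# named internal node, resolve ambiguity by the configured policy, convert
# the resolved association presences (with multiplicity) and block counts
# into blocks + adjacencies, and assemble. Every inclusion or exclusion
# carries a provenance record: parsimony cost, MPR state set, how the state
# was resolved, and any override applied.

config_defaults <- function(config = list()) {
  defaults <- list(
    policy = "missing", engine = "fitch", tie_break = "outgroup",
    outgroup = "AEK", contains = "7/10",
    overrides = xen_overrides(),
    assignments = xen_block_assignments()
  )
  for (nm in names(config)) defaults[[nm]] <- config[[nm]]
  defaults
}

outgroup_state_for <- function(matrix, character, outgroup) {
  st <- character_states(matrix, character)
  row <- st[st$taxon == outgroup, ]
  if (nrow(row) == 0 || row$status[1] == "missing") return(NA_integer_)
  row$state_min[1]
}

#' Reconstruct every character of a matrix on a tree
#'
#' Associations are reconstructed by the configured engine (Fitch by
#' default, Dollo on request) on presence/absence plus ordered (Wagner)
#' parsimony on occurrence counts for multiplicity; fragment counts by
#' Wagner parsimony.
#'
#' @param matrix A `karyo_matrix`.
#' @param tree Rooted `phylo` whose tips cover the matrix taxa.
#' @param config Configuration list, see [study_config()].
#' @return Named list of `karyo_reconstruction` objects (association
#'   characters carry the count reconstruction in `$multiplicity`).
#' @export
reconstruct_characters <- function(matrix, tree, config = study_config()) {
  config <- config_defaults(config)
  chars <- attr(matrix, "characters")
  recs <- purrr::pmap(chars, function(character, kind) {
    st <- character_states(matrix, character)
    if (kind == "association") {
      rec <- if (config$engine == "dollo") {
        dollo_reconstruct(tree, st, character)
      } else {
        fitch_reconstruct(tree, st, character)
      }
      rec$multiplicity <- wagner_counts(tree, st, paste0(character, " (multiplicity)"))
      rec
    } else {
      wagner_counts(tree, st, character)
    }
  })
  setNames(recs, chars$character)
}

#' Infer an ancestral karyotype at a named node
#'
#' Runs parsimony per character, resolves states at `node` under the
#' configured tie-break policy and override table, converts the resolved
#' states into blocks and adjacencies, and assembles the karyotype.
#' With `config$tie_break = "report"`, characters left ambiguous at the node
#' are returned as labeled variants rather than silently chosen.
#'
#' @param maps Named list of [painting_map()] objects (including the
#'   outgroup pseudo-taxon named by `config$outgroup`).
#' @param tree Rooted `phylo`.
#' @param node Internal node name (e.g. `"Xenarthra"`) or a tip name (a tip
#'   returns its own karyotype content).
#' @param config See [study_config()].
#' @return An `ancestral_karyotype` with a per-character `provenance` tibble
#'   and a `variants` tibble listing ambiguous alternatives (e.g. the HSA 6
#'   two-block variant).
#' @export
infer_ancestral_karyotype <- function(maps, tree, node, config = study_config()) {
  config <- config_defaults(config)
  matrix <- build_character_matrix(maps, policy = config$policy,
                                   contains = config$contains)
  node_number(tree, node)  # validates the node name
  recs <- reconstruct_characters(matrix, tree, config)

  ov <- config$overrides
  prov <- list(); variants <- list()
  states <- purrr::imap(recs, function(rec, ch) {
    o <- ov[ov$character == ch, ]
    res_override <- if (nrow(o) > 0 && o$kind[1] == "resolution") o else NULL
    og_state <- outgroup_state_for(matrix, ch, config$outgroup)
    if (rec$engine == "fitch") og_state <- min(og_state, 1L)
    res <- resolve_ambiguity(
      rec, policy = "outgroup",
      outgroup_state = if (is.na(og_state)) NULL else og_state,
      override = res_override
    )
    s <- resolved_state(res, node)
    how <- res$states$resolved_by[res$states$node == node]
    mpr_set <- rec$node_states[[node]]
    note <- res$states$note[res$states$node == node]
    if (nrow(o) > 0 && o$kind[1] == "assertion" &&
        identical(o$node[1], node) && s != o$state[1]) {
      note <- paste0(o$note[1], " [parsimony interval at ", node, ": ",
                     paste(mpr_set, collapse = "-"), "]")
      s <- o$state[1]
      how <- "assertion"
    }
    if (length(mpr_set) > 1 && how %in% c("parent_deltran", "outgroup")) {
      alts <- setdiff(mpr_set, s)
      variants[[ch]] <<- tibble(character = ch, state = s, alternatives = I(list(alts)))
    }
    mult <- NA_integer_
    if (rec$engine %in% c("fitch", "dollo") && s >= 1) {
      mres <- resolve_ambiguity(rec$multiplicity, policy = "outgroup",
                                outgroup_state = if (is.na(og_state)) 0L else
                                  outgroup_state_for(matrix, ch, config$outgroup))
      mult <- max(1L, resolved_state(mres, node))
    }
    prov[[ch]] <<- tibble(
      character = ch, kind = if (rec$engine == "wagner") "fragment_count" else "association",
      cost = rec$cost, mpr_states = paste(mpr_set, collapse = "|"),
      state = s, multiplicity = mult, resolved_by = how,
      note = if (length(note) > 0) note[1] else NA_character_
    )
    s
  })
  prov <- bind_rows(prov)
  variants <- if (length(variants) > 0) bind_rows(variants) else
    tibble(character = character(), state = integer(), alternatives = list())

  chars <- attr(matrix, "characters")
  counts <- prov |>
    filter(.data$kind == "fragment_count") |>
    mutate(hsa = sub("^HSA", "", .data$character)) |>
    select("hsa", count = "state")
  present <- prov |>
    filter(.data$kind == "association", .data$state >= 1)

  assigns <- config$assignments
  # blocks already reserved by the packaged assignment table must not be
  # re-used when falling back to free-block allocation (simulated data)
  used <- new.env()
  reserve <- function(h, idx) {
    assign(h, union(get0(h, envir = used, ifnotfound = integer()), idx),
           envir = used)
  }
  next_free <- function(h) {
    idx <- setdiff(seq_len(1000L), get0(h, envir = used, ifnotfound = integer()))[1]
    reserve(h, idx)
    idx
  }
  packaged <- purrr::pmap(present, function(character, multiplicity, ...) {
    a <- assigns[assigns$character == character, ]
    if (nrow(a) == 0) return(NULL)
    a <- filter(a, .data$occurrence <= max(1L, multiplicity, na.rm = TRUE))
    purrr::pwalk(a, function(hsa, block_index, ...) reserve(hsa, block_index))
    a
  }) |> purrr::compact() |> bind_rows()
  fallback <- purrr::pmap(present, function(character, multiplicity, ...) {
    if (nrow(assigns[assigns$character == character, ]) > 0) return(NULL)
    mem <- association_members(character)
    purrr::map(seq_len(max(1L, multiplicity, na.rm = TRUE)), function(occ) {
      tibble(character = character, occurrence = occ, hsa = mem,
             block_index = vapply(mem, next_free, integer(1)))
    }) |> bind_rows()
  }) |> purrr::compact() |> bind_rows()
  adj <- bind_rows(packaged, fallback)

  sex_n <- if (!is.null(maps[[config$outgroup]]))
    maps[[config$outgroup]]$sex_chromosome_count else 2L
  k <- assemble_karyotype(counts, adj, sex_chromosome_count = sex_n,
                          provenance = prov)
  k$variants <- variants
  k$node <- node
  k$config <- config
  k
}
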