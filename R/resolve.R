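# Ambiguity resolution. MPR state sets leave internal nodes ambiguous
# wherever reconstructions disagree; the "outgroup" policy resolves them
# toward a reference state -- by default the ancestral Eutherian karyotype's
# state for the character, with an explicit per-character override table
# (deep-outgroup evidence such as opossum/chicken synteny) consulted first.
# Descendant nodes are then resolved top-down preferring the parent's state
# whenever it remains optimal, i.e. changes are pushed tipward (DELTRAN);
# the policy used is always recorded, never silently chosen.

#' Resolve ambiguous ancestral states
#'
#' @param rec A `karyo_reconstruction` from [fitch_reconstruct()] or
#'   [wagner_counts()].
#' @param policy `"outgroup"` resolves every node; `"report"` leaves
#'   ambiguity in place (states stay sets).
#' @param outgroup_state Reference state (the outgroup/ancestral karyotype's
#'   state for this character). Required for `policy = "outgroup"`.
#' @param override Optional one-row tibble (`character`, `state`, `note`)
#'   asserting a deep-outgroup state for this character; consulted before
#'   `outgroup_state`. Its `character` must match the reconstruction's.
#' @return A `karyo_resolution`: `$states` (tibble `node`, `state`,
#'   `resolved_by`, `note`), `$events` (the single resolved history), and
#'   `$policy`.
#' @export
resolve_ambiguity <- function(rec, policy = c("outgroup", "report"),
                              outgroup_state = NULL, override = NULL) {
  policy <- match.arg(policy)
  phy <- rec$tree
  nm <- node_names(phy)
  n_tip <- length(phy$tip.label)

  if (!is.null(override)) {
    if (!override$character[1] %in% c(rec$character)) {
      abort(paste0("override references unknown character: ", override$character[1]))
    }
  }

  if (policy == "report") {
    states <- tibble(
      node = names(rec$node_states),
      state = unname(purrr::map_chr(rec$node_states, paste, collapse = "|")),
      resolved_by = if_else(unname(rec$ambiguous), "unresolved", "unambiguous"),
      note = NA_character_
    )
    return(structure(list(states = states, events = NULL, policy = policy,
                          character = rec$character),
                     class = "karyo_resolution"))
  }

  # the root is polarized by the outgroup state; the override (deep-outgroup
  # evidence for this character) is consulted at descendant ambiguous nodes
  root_target <- outgroup_state %||% override$state[1] %||% NA_integer_
  override_state <- if (!is.null(override)) override$state[1] else NA_integer_
  override_note <- if (!is.null(override)) override$note[1] else NA_character_

  if (rec$engine == "dollo") {
    # single reconstruction, nothing to resolve
    states <- tibble(node = names(rec$node_states),
                     state = as.integer(unlist(rec$node_states)),
                     resolved_by = "unambiguous", note = NA_character_)
    return(structure(list(states = states, events = rec$events, policy = policy,
                          character = rec$character),
                     class = "karyo_resolution"))
  }

  U <- rec$engine_data$U
  alphabet <- rec$alphabet
  step <- abs(outer(alphabet, alphabet, "-"))
  kids <- children_of(phy)
  root <- root_of(phy)

  chosen <- setNames(rep(NA_integer_, length(nm)), nm)
  how <- setNames(rep(NA_character_, length(nm)), nm)

  pick <- function(cand, pref) {
    # closest to pref; ties toward the smaller state
    cand[order(abs(cand - pref), cand)][1]
  }

  root_opt <- alphabet[which(U[root, ] == min(U[root, ]))]
  if (length(root_opt) > 1 && is.na(root_target)) {
    abort("policy 'outgroup' needs an outgroup_state (or an override) to resolve an ambiguous root")
  }
  chosen[nm[root]] <- if (length(root_opt) == 1) root_opt else pick(root_opt, root_target)
  how[nm[root]] <- if (length(root_opt) > 1) "outgroup" else "unambiguous"

  resolve_down <- function(v) {
    if (v <= n_tip) return(invisible())
    sv <- chosen[nm[v]]
    si <- match(sv, alphabet)
    for (c in kids[[v]]) {
      if (c <= n_tip) next
      vals <- step[si, ] + U[c, ]
      cand <- alphabet[which(vals == min(vals))]
      if (length(cand) == 1) {
        chosen[nm[c]] <<- cand
        how[nm[c]] <<- "unambiguous"
      } else if (!is.na(override_state) && override_state %in% cand) {
        chosen[nm[c]] <<- override_state
        how[nm[c]] <<- "override"
      } else if (sv %in% cand) {
        # delay changes tipward (DELTRAN) when the parent state stays optimal
        chosen[nm[c]] <<- sv
        how[nm[c]] <<- "parent_deltran"
      } else {
        chosen[nm[c]] <<- pick(cand, sv)
        how[nm[c]] <<- "parent_nearest"
      }
      resolve_down(c)
    }
  }
  resolve_down(root)

  # tips: observed value nearest the parent within their interval
  par <- parent_of(phy)
  for (t in seq_len(n_tip)) {
    ts <- rec$tip_states[rec$tip_states$taxon == phy$tip.label[t], ]
    p_state <- chosen[nm[par[t]]]
    if (ts$status[1] == "missing" || is.na(ts$state_min[1])) {
      chosen[nm[t]] <- p_state
      how[nm[t]] <- "missing_follows_parent"
    } else {
      chosen[nm[t]] <- min(max(p_state, ts$state_min[1]), ts$state_max[1])
      how[nm[t]] <- "tip"
    }
  }

  assignment <- setNames(chosen[nm[(n_tip + 1):length(nm)]],
                         as.character((n_tip + 1):length(nm)))
  events <- events_from_assignment(
    phy, as.list(assignment), rec$tip_states,
    kind = if (rec$engine == "fitch") "binary" else "count"
  )
  states <- tibble(
    node = nm, state = unname(chosen), resolved_by = unname(how),
    note = dplyr::case_when(
      how == "override" ~ override_note,
      how == "outgroup" ~ paste0("root polarized toward outgroup state ", root_target),
      TRUE ~ NA_character_
    )
  )
  structure(list(states = states, events = events, policy = policy,
                 character = rec$character),
            class = "karyo_resolution")
}

#' @export
print.karyo_resolution <- function(x, ...) {
  cat("<karyo_resolution> ", x$character, " [policy: ", x$policy, "]\n", sep = "")
  print(x$states, n = 5)
  invisible(x)
}

resolved_state <- function(res, node) {
  s <- res$states$state[res$states$node == node]
  if (length(s) == 0) abort(paste0("unknown node: ", node))
  s[1]
}
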