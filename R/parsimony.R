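# Ancestral-state reconstruction engines. All engines share one generalized
# (Sankoff) dynamic program over an integer state alphabet with linear step
# cost |i - j|, which reduces to unweighted Fitch parsimony on {0,1} and to
# ordered (Wagner) parsimony on counts. Most parsimonious reconstructions
# (MPRs) are enumerated exhaustively on small trees; tips with missing states
# constrain nothing, and interval states (printed "a?" ranges) are free
# within their bounds.

# tip_states: tibble(taxon, state_min, state_max, status) -- status "missing"
# means unconstrained. Returns per-tip cost rows over `alphabet`.
tip_cost_matrix <- function(phy, tip_states, alphabet) {
  n_tip <- length(phy$tip.label)
  cost <- matrix(Inf, n_tip, length(alphabet),
                 dimnames = list(phy$tip.label, alphabet))
  miss <- setdiff(phy$tip.label, tip_states$taxon)
  if (length(miss) > 0) {
    abort(paste0("tip(s) in tree missing from states: ", paste(miss, collapse = ", ")))
  }
  for (i in seq_len(nrow(tip_states))) {
    t <- tip_states$taxon[i]
    if (!t %in% phy$tip.label) {
      abort(paste0("taxon absent from tree: ", t))
    }
    if (tip_states$status[i] == "missing" || is.na(tip_states$state_min[i])) {
      cost[t, ] <- 0
    } else {
      ok <- alphabet >= tip_states$state_min[i] & alphabet <= tip_states$state_max[i]
      cost[t, ok] <- 0
    }
  }
  cost
}

sankoff_up <- function(phy, tipcost, alphabet) {
  n_tip <- length(phy$tip.label)
  n_all <- n_tip + phy$Nnode
  k <- length(alphabet)
  U <- matrix(Inf, n_all, k)
  U[seq_len(n_tip), ] <- tipcost[phy$tip.label, , drop = FALSE]
  kids <- children_of(phy)
  step <- abs(outer(alphabet, alphabet, "-"))
  for (v in postorder_nodes(phy)) {
    if (v <= n_tip) next
    acc <- rep(0, k)
    for (c in kids[[v]]) {
      # min over child state t of step(s,t) + U[c,t], vectorized over s
      acc <- acc + apply(step + rep(U[c, ], each = k), 1, min)
    }
    U[v, ] <- acc
  }
  U
}

# Exhaustive enumeration of internal-node assignments achieving minimum cost.
enumerate_mprs <- function(phy, U, alphabet, max_mpr = 20000L) {
  n_tip <- length(phy$tip.label)
  kids <- children_of(phy)
  root <- root_of(phy)
  step <- abs(outer(alphabet, alphabet, "-"))
  truncated <- FALSE

  expand <- function(v, allowed_idx) {
    # returns list of assignments (named int vectors over internal nodes of
    # the subtree at v), one per optimal completion with v's state in allowed
    if (v <= n_tip) return(list(setNames(integer(0), character(0))))
    res <- list()
    for (si in allowed_idx) {
      parts <- list(list(setNames(alphabet[si], as.character(v))))
      for (c in kids[[v]]) {
        vals <- step[si, ] + U[c, ]
        copt <- which(vals == min(vals))
        sub <- expand(c, copt)
        parts[[length(parts) + 1]] <- sub
      }
      combos <- Reduce(function(a, b) {
        out <- list()
        for (x in a) for (y in b) {
          out[[length(out) + 1]] <- c(x, y)
          if (length(out) > max_mpr) break
        }
        out
      }, parts)
      res <- c(res, combos)
      if (length(res) > max_mpr) {
        truncated <<- TRUE
        res <- res[seq_len(max_mpr)]
        break
      }
    }
    res
  }

  root_opt <- which(U[root, ] == min(U[root, ]))
  mprs <- expand(root, root_opt)
  mprs <- unique(mprs)
  list(mprs = mprs, truncated = truncated)
}

# Per-node MPR state sets via up+down costs (exact, no enumeration needed).
mpr_state_sets <- function(phy, U, alphabet) {
  n_tip <- length(phy$tip.label)
  n_all <- n_tip + phy$Nnode
  k <- length(alphabet)
  kids <- children_of(phy)
  par <- parent_of(phy)
  root <- root_of(phy)
  step <- abs(outer(alphabet, alphabet, "-"))
  D <- matrix(Inf, n_all, k)
  D[root, ] <- 0
  for (v in rev(postorder_nodes(phy))) {
    if (v <= n_tip) next
    for (c in kids[[v]]) {
      sib <- setdiff(kids[[v]], c)
      sibcost <- rep(0, k)
      for (b in sib) {
        sibcost <- sibcost + apply(step + rep(U[b, ], each = k), 1, min)
      }
      # D[c,s] = min over parent state t of D[v,t] + sibcost[t] + step(t,s)
      base <- D[v, ] + sibcost
      D[c, ] <- apply(step + rep(base, each = k), 2, min)
    }
  }
  total <- min(U[root, ])
  sets <- vector("list", n_all)
  for (v in seq_len(n_all)) {
    sets[[v]] <- alphabet[which(U[v, ] + D[v, ] <= total + 1e-9)]
  }
  names(sets) <- node_names(phy)
  sets
}

events_from_assignment <- function(phy, assignment, tip_states, kind) {
  n_tip <- length(phy$tip.label)
  nm <- node_names(phy)
  rows <- list()
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]; c <- phy$edge[i, 2]
    from <- assignment[[as.character(p)]]
    if (c <= n_tip) {
      ts <- tip_states[tip_states$taxon == phy$tip.label[c], ]
      if (ts$status[1] == "missing" || is.na(ts$state_min[1])) next
      to <- min(max(from, ts$state_min[1]), ts$state_max[1])
    } else {
      to <- assignment[[as.character(c)]]
    }
    if (is.na(to) || to == from) next
    type <- if (kind == "binary") {
      if (to > from) "gain" else "loss"
    } else {
      if (to > from) paste0("+", to - from) else as.character(to - from)
    }
    rows[[length(rows) + 1]] <- tibble(
      parent = nm[p], child = nm[c], from = from, to = to, type = type
    )
  }
  if (length(rows) == 0) {
    return(tibble(parent = character(), child = character(),
                  from = integer(), to = integer(), type = character()))
  }
  bind_rows(rows)
}

new_reconstruction <- function(character, engine, phy, alphabet, tip_states,
                               U, cost, node_states, mprs, events, method,
                               truncated = FALSE) {
  nm <- node_names(phy)
  structure(
    list(
      character = character, engine = engine, tree = phy, alphabet = alphabet,
      tip_states = tip_states, cost = cost, node_states = node_states,
      mprs = mprs, events = events, method = method, truncated = truncated,
      ambiguous = vapply(node_states, function(s) length(s) > 1, logical(1)),
      engine_data = list(U = U)
    ),
    class = "karyo_reconstruction"
  )
}

reconstruct_linear <- function(phy, tip_states, character, engine, alphabet,
                               kind, max_enumerate_tips = 15L) {
  tipcost <- tip_cost_matrix(phy, tip_states, alphabet)
  U <- sankoff_up(phy, tipcost, alphabet)
  root <- root_of(phy)
  cost <- min(U[root, ])
  sets <- mpr_state_sets(phy, U, alphabet)
  if (length(phy$tip.label) <= max_enumerate_tips) {
    en <- enumerate_mprs(phy, U, alphabet)
    mprs <- purrr::map(en$mprs, function(a) setNames(a, node_names(phy)[as.integer(names(a))]))
    events <- purrr::imap(en$mprs, function(a, i) {
      ev <- events_from_assignment(phy, a, tip_states, kind)
      ev$mpr <- rep(i, nrow(ev))
      ev
    }) |> bind_rows()
    if (is.null(events$mpr)) events$mpr <- integer(0)
    method <- "mpr_enumeration"
    truncated <- en$truncated
  } else {
    mprs <- list()
    events <- tibble(parent = character(), child = character(),
                     from = integer(), to = integer(), type = character(),
                     mpr = integer())
    method <- "sankoff_state_sets"
    truncated <- FALSE
  }
  new_reconstruction(character, engine, phy, alphabet, tip_states, U, cost,
                     sets, mprs, events, method, truncated)
}

normalize_states <- function(states) {
  if (is.data.frame(states)) return(as_tibble(states))
  # named vector: NA = missing
  tibble(
    taxon = names(states),
    state_min = as.integer(states), state_max = as.integer(states),
    status = if_else(is.na(states), "missing", "observed")
  )
}

#' Fitch parsimony with full MPR enumeration
#'
#' Unweighted minimum-change reconstruction of a binary (present/absent)
#' character on a rooted tree. On trees of at most `max_enumerate_tips` tips
#' every most parsimonious reconstruction is enumerated; larger trees fall
#' back to exact per-node state sets without event placements, with the
#' method recorded. Missing tips constrain nothing. Polytomies are handled
#' natively by the dynamic program.
#'
#' @param tree A rooted `phylo`.
#' @param states Tibble (`taxon`, `state_min`, `state_max`, `status`) as from
#'   [character_states()], or a named vector with `NA` for missing. Counts
#'   above 1 are treated as present.
#' @param character Character identity carried into the result.
#' @param max_enumerate_tips Enumeration size guard.
#' @return A `karyo_reconstruction`: minimum cost, per-node MPR state sets,
#'   the enumerated MPR assignments and their event placements.
#' @export
fitch_reconstruct <- function(tree, states, character = "character",
                              max_enumerate_tips = 15L) {
  st <- normalize_states(states) |>
    mutate(state_min = pmin(.data$state_min, 1L),
           state_max = pmin(.data$state_max, 1L))
  reconstruct_linear(tree, st, character, "fitch", alphabet = 0:1,
                     kind = "binary", max_enumerate_tips = max_enumerate_tips)
}

#' Ordered (Wagner) parsimony for integer count characters
#'
#' Minimizes the sum of |parent - child| over branches. Tip ranges (printed
#' "?" intervals) are free within their bounds; missing tips constrain
#' nothing. Per-node optimal-state sets are intervals.
#'
#' @inheritParams fitch_reconstruct
#' @return A `karyo_reconstruction`.
#' @export
wagner_counts <- function(tree, states, character = "character",
                          max_enumerate_tips = 15L) {
  st <- normalize_states(states)
  obs <- c(st$state_min, st$state_max)
  obs <- obs[!is.na(obs)]
  if (length(obs) == 0) abort("no observed counts")
  alphabet <- seq(min(obs), max(obs))
  if (length(alphabet) == 1) alphabet <- c(alphabet, alphabet + 1L)
  reconstruct_linear(tree, st, character, "wagner", alphabet = alphabet,
                     kind = "count", max_enumerate_tips = max_enumerate_tips)
}

#' Dollo parsimony
#'
#' A single origin of the derived (present) state is permitted, with
#' unlimited losses: the gain is placed on the stem of the smallest clade
#' spanning all present tips, and losses on the minimal set of branches
#' leading to observed-absent descendants. Cost = 1 + losses.
#'
#' @inheritParams fitch_reconstruct
#' @return A `karyo_reconstruction` (a single reconstruction; never ambiguous).
#' @export
dollo_reconstruct <- function(tree, states, character = "character") {
  st <- normalize_states(states) |>
    mutate(state_min = pmin(.data$state_min, 1L),
           state_max = pmin(.data$state_max, 1L))
  phy <- tree
  n_tip <- length(phy$tip.label)
  nm <- node_names(phy)
  miss <- setdiff(phy$tip.label, st$taxon)
  if (length(miss) > 0) {
    abort(paste0("tip(s) in tree missing from states: ", paste(miss, collapse = ", ")))
  }
  present <- st$taxon[st$status != "missing" & !is.na(st$state_min) & st$state_min >= 1]
  absent <- st$taxon[st$status != "missing" & !is.na(st$state_max) & st$state_max == 0]

  state <- setNames(rep(0L, n_tip + phy$Nnode), nm)
  state[present] <- 1L
  events <- tibble(parent = character(), child = character(),
                   from = integer(), to = integer(), type = character(),
                   mpr = integer())
  if (length(present) > 0) {
    g <- if (length(present) == 1) {
      match(present, phy$tip.label)
    } else {
      ape::getMRCA(phy, present)
    }
    kids <- children_of(phy)
    par <- parent_of(phy)
    # mark nodes inside the clade whose subtree holds a present tip
    marked <- rep(FALSE, n_tip + phy$Nnode)
    has_absent <- rep(FALSE, n_tip + phy$Nnode)
    for (v in postorder_nodes(phy)) {
      if (v <= n_tip) {
        marked[v] <- phy$tip.label[v] %in% present
        has_absent[v] <- phy$tip.label[v] %in% absent
      } else {
        marked[v] <- any(marked[kids[[v]]])
        has_absent[v] <- any(has_absent[kids[[v]]])
      }
    }
    in_clade <- rep(FALSE, n_tip + phy$Nnode)
    mark_clade <- function(v) {
      in_clade[v] <<- TRUE
      if (v > n_tip) for (k in kids[[v]]) mark_clade(k)
    }
    mark_clade(g)
    state[nm[in_clade & marked]] <- 1L
    ev <- list()
    gp <- par[g]
    ev[[1]] <- tibble(parent = if (is.na(gp)) NA_character_ else nm[gp],
                      child = nm[g], from = 0L, to = 1L, type = "gain", mpr = 1L)
    for (v in which(in_clade & marked)) {
      if (v <= n_tip) next
      for (k in kids[[v]]) {
        if (!marked[k] && has_absent[k]) {
          ev[[length(ev) + 1]] <- tibble(parent = nm[v], child = nm[k],
                                         from = 1L, to = 0L, type = "loss", mpr = 1L)
        }
      }
    }
    events <- bind_rows(ev)
  }
  cost <- if (length(present) == 0) 0 else sum(events$type == "loss") + 1
  node_states <- lapply(state, function(s) s)
  assignment <- state[(n_tip + 1):(n_tip + phy$Nnode)]
  new_reconstruction(character, "dollo", phy, 0:1, st, U = NULL, cost = cost,
                     node_states = node_states, mprs = list(assignment),
                     events = events, method = "dollo_single_origin")
}

#' Brute-force minimum-change oracle
#'
#' Exhaustively enumerates every assignment of states to internal nodes and
#' returns the minimum total |parent - child| cost and all optimal
#' assignments. Authoritative for tests; refuses trees with more than 12
#' internal nodes.
#'
#' @inheritParams fitch_reconstruct
#' @param alphabet Integer states to enumerate over (default: range observed).
#' @return List with `cost` and `assignments` (named integer vectors).
#' @export
brute_force_min_changes <- function(tree, states, alphabet = NULL) {
  st <- normalize_states(states)
  phy <- tree
  if (phy$Nnode > 12) abort("brute force refuses trees with > 12 internal nodes")
  obs <- c(st$state_min, st$state_max)
  obs <- obs[!is.na(obs)]
  if (is.null(alphabet)) alphabet <- seq(min(obs), max(obs))
  if (length(alphabet) == 1) alphabet <- c(alphabet, alphabet + 1L)
  n_tip <- length(phy$tip.label)
  nm <- node_names(phy)
  internal <- (n_tip + 1):(n_tip + phy$Nnode)
  grid <- as.matrix(expand.grid(rep(list(alphabet), phy$Nnode)))
  tip_tab <- st[match(phy$tip.label, st$taxon), ]
  costs <- numeric(nrow(grid))
  col_of <- function(node) grid[, node - n_tip, drop = TRUE]
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]; c <- phy$edge[i, 2]
    if (c <= n_tip) {
      ts <- tip_tab[c, ]
      if (ts$status == "missing" || is.na(ts$state_min)) next
      costs <- costs + pmax(0, ts$state_min - col_of(p), col_of(p) - ts$state_max)
    } else {
      costs <- costs + abs(col_of(p) - col_of(c))
    }
  }
  best <- min(costs)
  assignments <- lapply(which(costs == best), function(i) {
    setNames(as.integer(grid[i, ]), nm[internal])
  })
  list(cost = best, assignments = assignments)
}

#' @export
print.karyo_reconstruction <- function(x, ...) {
  cat("<karyo_reconstruction> ", x$character, " [", x$engine, "]\n", sep = "")
  cat("  cost: ", x$cost, "; MPRs enumerated: ", length(x$mprs),
      "; method: ", x$method, "\n", sep = "")
  amb <- names(x$ambiguous)[x$ambiguous]
  if (length(amb) > 0) cat("  ambiguous nodes:", paste(amb, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.karyo_reconstruction <- function(x, ...) {
  tibble(
    node = names(x$node_states),
    states = unname(purrr::map_chr(x$node_states, paste, collapse = "|")),
    ambiguous = unname(x$ambiguous)
  ) |> mutate(character = x$character, engine = x$engine, .before = 1)
}

#' @export
glance.karyo_reconstruction <- function(x, ...) {
  tibble(
    character = x$character, engine = x$engine, cost = x$cost,
    n_mprs = length(x$mprs), n_ambiguous_nodes = sum(x$ambiguous),
    method = x$method, truncated = x$truncated
  )
}
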