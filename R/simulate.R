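# Synthetic-data generator: karyotype evolution by whole-chromosome fusions
# and block fissions along a tree, starting from an assembled ancestral
# karyotype. These are the only two event types the painting-character
# system can observe. Each branch draws Poisson numbers of events (expected
# rate * branch length); a fusion joins two uniformly chosen chromosomes
# end to end, a fission splits a uniformly chosen block in two. The sex
# chromosome never participates. Every run is reproducible from its seed
# and emits a ground-truth event log plus the true karyotype at every node.

#' Simulation configuration
#'
#' @param tree Rooted `phylo`; branch lengths default to 1 where absent.
#' @param ancestor An `ancestral_karyotype` to seed the root (default: the
#'   packaged ancestral Eutherian karyotype).
#' @param fusion_rate,fission_rate Expected events per unit branch length.
#' @param probe_failure_prob Per taxon, per human chromosome: probability
#'   the probe yields no data.
#' @param unpainted_pair_prob Per tip chromosome: probability the pair goes
#'   entirely unpainted (emulating heterochromatic elements).
#' @param seed Mandatory integer seed.
#' @param forced_events Optional tibble (`branch` = child node name, `type`,
#'   `block_a`, `block_b`) of events applied deterministically before any
#'   random events on that branch; for fusions both blocks must be
#'   chromosome ends.
#' @return A `sim_config` list.
#' @export
sim_config <- function(tree, ancestor = NULL, fusion_rate = 0.1,
                       fission_rate = 0.1, probe_failure_prob = 0,
                       unpainted_pair_prob = 0, seed,
                       forced_events = NULL) {
  if (missing(seed)) abort("a seed is mandatory for reproducibility")
  if (fusion_rate < 0 || fission_rate < 0) abort("rates must be >= 0")
  if (is.null(ancestor)) ancestor <- aek_karyotype()
  structure(list(
    tree = tree, ancestor = ancestor, fusion_rate = fusion_rate,
    fission_rate = fission_rate, probe_failure_prob = probe_failure_prob,
    unpainted_pair_prob = unpainted_pair_prob, seed = as.integer(seed),
    forced_events = forced_events
  ), class = "sim_config")
}

#' The packaged ancestral Eutherian karyotype as an assembled object
#'
#' Rebuilds the ancestral Eutherian karyotype from its printed block
#' composition through the assembly machinery (blocks + adjacencies ->
#' connected components -> diploid number).
#'
#' @param variant `"aek"` (2n = 48) or `"alt"` (2n = 46, with the
#'   additional 10p/12/22 association).
#' @return An `ancestral_karyotype`.
#' @export
aek_karyotype <- function(variant = c("aek", "alt")) {
  variant <- match.arg(variant)
  map <- xen_painting_maps()[[if (variant == "aek") "AEK" else "AEKALT"]]
  map_to_karyotype(map)
}

#' Assemble a painting map into a karyotype object
#'
#' Converts a painting map's chromosome structure into the block/adjacency
#' representation and reassembles it, so that map-level and assembly-level
#' arithmetic can be compared directly. Uncertain segments are included.
#'
#' @param map A [painting_map()].
#' @return An `ancestral_karyotype`.
#' @export
map_to_karyotype <- function(map) {
  seg <- map$segments |>
    arrange(match(.data$chrom_id, map$chromosomes$chrom_id), .data$seg) |>
    group_by(.data$hsa) |>
    mutate(block_index = row_number()) |>
    ungroup()
  blocks <- seg |> count(.data$hsa, name = "count") |>
    filter(.data$hsa != "Y")
  unpainted <- map$chromosomes$chrom_id[map$chromosomes$unpainted]
  if (length(unpainted) > 0) {
    # unpainted pairs exist as chromosomes of unknown content
    blocks <- bind_rows(blocks, tibble(
      hsa = paste0("unk", seq_along(unpainted)), count = 1L))
  }
  adj <- seg |>
    group_by(.data$chrom_id) |>
    filter(dplyr::n_distinct(.data$hsa) >= 2) |>
    mutate(character = association_id(unique(.data$hsa))) |>
    ungroup() |>
    arrange(match(.data$chrom_id, map$chromosomes$chrom_id), .data$seg)
  if (nrow(adj) > 0) {
    occ_id <- match(adj$chrom_id, unique(adj$chrom_id))
    adj <- adj |>
      mutate(occurrence = occ_id) |>
      select("character", "occurrence", "hsa", "block_index")
  } else {
    adj <- NULL
  }
  assemble_karyotype(blocks, adj,
                     sex_chromosome_count = map$sex_chromosome_count)
}

# internal karyotype representation during simulation: list of character
# vectors of block ids "hsa.instance"; the sex chromosome is "X.1".
karyo_to_simstate <- function(k) {
  counter <- new.env()
  relabel <- function(block) {
    hsa <- sub("[a-f]$", "", block)
    n <- (get0(hsa, envir = counter, ifnotfound = 0L)) + 1L
    assign(hsa, n, envir = counter)
    paste0(hsa, ".", n)
  }
  lapply(unname(k$chromosomes), function(chr) vapply(chr, relabel, character(1)))
}

sim_is_sex <- function(chr) any(startsWith(chr, "X.") | startsWith(chr, "Y."))

apply_fusion <- function(state, i, j, flip_i, flip_j) {
  a <- state[[i]]; b <- state[[j]]
  if (flip_i) a <- rev(a)
  if (flip_j) b <- rev(b)
  state[[i]] <- c(a, b)
  state[j] <- NULL
  state
}

apply_fission <- function(state, chr_idx, block_pos, next_id) {
  chr <- state[[chr_idx]]
  block <- chr[block_pos]
  hsa <- sub("\\..*$", "", block)
  left <- c(head(chr, block_pos - 1), paste0(hsa, ".", next_id))
  right <- c(paste0(hsa, ".", next_id + 1L), tail(chr, length(chr) - block_pos))
  state[[chr_idx]] <- left
  state[[length(state) + 1]] <- right
  state
}

simstate_blocks <- function(state) unlist(state, use.names = FALSE)

#' Simulate karyotype evolution along a tree
#'
#' @param config A [sim_config()].
#' @return List with `maps` (named list of [painting_map()] per tip, masking
#'   applied), `event_log` (tibble: `branch`, `index`, `type`, `detail`),
#'   `node_karyotypes` (true block lists at every node), and `config`.
#' @export
simulate_karyotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  phy <- config$tree
  set.seed(config$seed)
  bl <- phy$edge.length %||% rep(1, nrow(phy$edge))
  if (is.null(phy$edge.length)) bl <- rep(1, nrow(phy$edge))
  nm <- node_names(phy)
  n_tip <- length(phy$tip.label)
  kids <- children_of(phy)
  root <- root_of(phy)

  next_block_id <- new.env()
  assign("n", 0L, envir = next_block_id)
  fresh_ids <- function() {
    n <- get("n", envir = next_block_id)
    assign("n", n + 2L, envir = next_block_id)
    # ids beyond any initial instance number
    1000L + n
  }

  root_state <- karyo_to_simstate(config$ancestor)
  node_states <- vector("list", n_tip + phy$Nnode)
  node_states[[root]] <- root_state
  log_rows <- list()

  evolve_branch <- function(state, child_num) {
    branch_name <- nm[child_num]
    len <- bl[match(child_num, phy$edge[, 2])]
    if (is.na(len)) len <- 1
    events <- character(0)

    forced <- config$forced_events
    if (!is.null(forced)) {
      forced <- forced[forced$branch == branch_name, , drop = FALSE]
      for (i in seq_len(nrow(forced))) {
        if (forced$type[i] == "fusion") {
          loc <- function(b) which(vapply(state, function(ch) b %in% ch, logical(1)))
          ia <- loc(forced$block_a[i]); ib <- loc(forced$block_b[i])
          if (length(ia) != 1 || length(ib) != 1 || ia == ib) {
            abort(paste0("forced fusion operands not found on ", branch_name))
          }
          a <- state[[ia]]
          flip_a <- which(a == forced$block_a[i]) == 1
          b <- state[[ib]]
          flip_b <- which(b == forced$block_b[i]) != 1
          state <- apply_fusion(state, ia, ib, flip_a, flip_b)
          events <- c(events, paste0("fusion:", forced$block_a[i], "+", forced$block_b[i]))
        } else {
          loc <- which(vapply(state, function(ch) forced$block_a[i] %in% ch, logical(1)))
          pos <- which(state[[loc]] == forced$block_a[i])
          state <- apply_fission(state, loc, pos, fresh_ids())
          events <- c(events, paste0("fission:", forced$block_a[i]))
        }
      }
    }

    n_fus <- rpois(1, config$fusion_rate * len)
    n_fis <- rpois(1, config$fission_rate * len)
    todo <- sample(c(rep("fusion", n_fus), rep("fission", n_fis)))
    for (type in todo) {
      autosomes <- which(!vapply(state, sim_is_sex, logical(1)))
      if (type == "fusion") {
        if (length(autosomes) < 2) next  # no legal pair; refuse and log
        pair <- sample(autosomes, 2)
        flip <- runif(2) < 0.5
        a_end <- state[[pair[1]]][if (flip[1]) 1 else length(state[[pair[1]]])]
        b_end <- state[[pair[2]]][if (flip[2]) length(state[[pair[2]]]) else 1]
        state <- apply_fusion(state, pair[1], pair[2], flip[1], flip[2])
        events <- c(events, paste0("fusion:", a_end, "+", b_end))
      } else {
        blocks <- unlist(state[autosomes], use.names = FALSE)
        b <- if (length(blocks) == 1) blocks else sample(blocks, 1)
        loc <- which(vapply(state, function(ch) b %in% ch, logical(1)))
        pos <- which(state[[loc]] == b)
        state <- apply_fission(state, loc, pos, fresh_ids())
        events <- c(events, paste0("fission:", b))
      }
    }
    if (length(events) > 0) {
      log_rows[[length(log_rows) + 1]] <<- tibble(
        branch = branch_name, index = seq_along(events),
        type = sub(":.*$", "", events), detail = sub("^[a-z]+:", "", events)
      )
    }
    state
  }

  walk <- function(v) {
    for (c in kids[[v]]) {
      node_states[[c]] <<- evolve_branch(node_states[[v]], c)
      if (c > n_tip) walk(c)
    }
  }
  walk(root)

  event_log <- if (length(log_rows) > 0) bind_rows(log_rows) else
    tibble(branch = character(), index = integer(), type = character(),
           detail = character())

  maps <- lapply(seq_len(n_tip), function(t) {
    simstate_to_map(node_states[[t]], phy$tip.label[t],
                    unpainted_pair_prob = config$unpainted_pair_prob)
  })
  names(maps) <- phy$tip.label
  if (config$probe_failure_prob > 0) {
    maps <- mask_probes(maps, config$probe_failure_prob,
                        seed = config$seed + 1L)
  }
  names(node_states) <- nm
  list(maps = maps, event_log = event_log, node_karyotypes = node_states,
       config = config)
}

# Turn a simulation state into a painting map: per human chromosome, blocks
# get sub-letters a, b, c ... in order of appearance.
simstate_to_map <- function(state, taxon, unpainted_pair_prob = 0) {
  counts <- table(sub("\\..*$", "", simstate_blocks(state)))
  seen <- new.env()
  rows <- list(); chrom_rows <- list()
  for (i in seq_along(state)) {
    chr <- state[[i]]
    id <- sprintf("%s_%02d", taxon, i)
    is_sex <- sim_is_sex(chr)
    unpaint <- !is_sex && runif(1) < unpainted_pair_prob
    chrom_rows[[i]] <- tibble(chrom_id = id, is_sex = is_sex,
                              unpainted = unpaint)
    if (unpaint) next
    labs <- vapply(chr, function(b) {
      hsa <- sub("\\..*$", "", b)
      if (counts[[hsa]] == 1) return(hsa)
      k <- get0(b, envir = seen, ifnotfound = NA_character_)
      if (!is.na(k)) return(k)
      n <- get0(paste0(".n_", hsa), envir = seen, ifnotfound = 0L) + 1L
      assign(paste0(".n_", hsa), n, envir = seen)
      lab <- paste0(hsa, letters[n])
      assign(b, lab, envir = seen)
      lab
    }, character(1))
    parsed <- parse_block_label(labs)
    parsed$chrom_id <- id
    parsed$seg <- seq_along(labs)
    rows[[length(rows) + 1]] <- parsed
  }
  painting_map(
    segments = bind_rows(rows), chromosomes = bind_rows(chrom_rows),
    taxon = taxon, species = paste0("simulated ", taxon),
    diploid_number_reported = 2L * sum(!vapply(state, sim_is_sex, logical(1))) +
      2L,
    sex_chromosome_count = 2L,
    notes = "simulated"
  )
}

#' Mask probes in painting maps
#'
#' Per taxon, each human chromosome probe is independently dropped to
#' missing with the given probability: its segments disappear from the map
#' and the chromosome is recorded under `probes_failed`. Deterministic for
#' a given seed.
#'
#' @param maps Named list of [painting_map()] objects.
#' @param probe_failure_prob Drop probability per probe.
#' @param seed Integer seed.
#' @return The masked maps.
#' @export
mask_probes <- function(maps, probe_failure_prob, seed) {
  set.seed(seed)
  lapply(maps, function(m) {
    present <- setdiff(unique(m$segments$hsa), c("X", "Y"))
    drop <- present[runif(length(present)) < probe_failure_prob]
    if (length(drop) == 0) return(m)
    seg <- filter(m$segments, !(.data$hsa %in% drop))
    newly_empty <- setdiff(m$chromosomes$chrom_id, seg$chrom_id)
    chrom <- m$chromosomes |>
      mutate(unpainted = .data$unpainted |
               (.data$chrom_id %in% newly_empty & !.data$is_sex))
    # a chromosome whose probes all failed is indistinguishable from an
    # unpainted pair; sex chromosomes keep their identity
    painting_map(
      segments = seg, chromosomes = chrom, taxon = m$taxon,
      species = m$species,
      diploid_number_reported = m$diploid_number_reported,
      sex_chromosome_count = m$sex_chromosome_count,
      probes_failed = sort(union(m$probes_failed, drop)),
      notes = m$notes
    )
  })
}

#' Events on the path from the root to a node
#'
#' @param sim Output of [simulate_karyotypes()].
#' @param node Node (tip) name.
#' @return The event-log rows on that path.
#' @export
events_on_path <- function(sim, node) {
  phy <- sim$config$tree
  nm <- node_names(phy)
  par <- parent_of(phy)
  v <- node_number(phy, node)
  path <- character(0)
  while (!is.na(par[v])) {
    path <- c(path, nm[v])
    v <- par[v]
  }
  sim$event_log[sim$event_log$branch %in% path, , drop = FALSE]
}
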