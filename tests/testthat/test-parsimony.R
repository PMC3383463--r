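test_that("Fitch reconstructions of the key binary characters match brute force and the known histories", {
  # 11/19: two isolated bearers, two convergent gains, not ancestral
  rec <- fitch_reconstruct(xtree, character_states(xmatrix, "11/19"), "11/19")
  bf <- brute_force_min_changes(xtree, character_states(xmatrix, "11/19"))
  expect_equal(rec$cost, 2)
  expect_equal(rec$cost, bf$cost)
  expect_equal(rec$node_states$Xenarthra, 0)

  # 2/8: three bearers, three convergent gains, not ancestral
  rec <- fitch_reconstruct(xtree, character_states(xmatrix, "2/8"), "2/8")
  expect_equal(rec$cost, 3)
  expect_equal(rec$node_states$Xenarthra, 0)
  expect_equal(length(rec$mprs), 1)
  ev <- rec$events
  expect_setequal(ev$child[ev$type == "gain"], c("CDI", "ESE", "TTE"))

  # constant character: zero cost, every node fixed
  rec <- fitch_reconstruct(xtree, character_states(xmatrix, "4/8"), "4/8")
  expect_equal(rec$cost, 0)
  expect_true(all(vapply(rec$node_states, identical, logical(1), 1L)))

  # 16/19: ancestral, cost 2, exactly the two published loss scenarios
  rec <- fitch_reconstruct(xtree, character_states(xmatrix, "16/19"), "16/19")
  expect_equal(rec$cost, 2)
  expect_equal(rec$node_states$Xenarthra, 1)
  expect_equal(length(rec$mprs), 2)
  scenarios <- lapply(seq_along(rec$mprs), function(i) {
    ev <- rec$events[rec$events$mpr == i, ]
    paste(sort(paste(ev$type, ev$child)), collapse = "; ")
  })
  expect_setequal(
    unlist(scenarios),
    c("loss Bradypus; loss CDI",        # lost twice independently
      "gain CHO; loss Folivora")        # lost once, regained in C. hoffmanni
  )
})

test_that("MPR state sets and enumerated assignments agree with the brute-force oracle", {
  set.seed(101)
  n_checked <- 0
  for (i in 1:60) {
    phy <- random_rooted_tree(sample(4:8, 1))
    st <- random_binary_states(phy$tip.label)
    if (all(is.na(st))) next
    rec <- fitch_reconstruct(phy, st)
    bf <- brute_force_min_changes(phy, st, alphabet = 0:1)
    expect_equal(rec$cost, bf$cost)
    ser <- function(a) paste(names(a), a, sep = "=", collapse = ",")
    expect_setequal(vapply(rec$mprs, ser, character(1)),
                    vapply(bf$assignments, ser, character(1)))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 50)
})

test_that("Fitch cost equals the brute-force oracle on 500 random characters", {
  set.seed(202)
  for (i in 1:500) {
    phy <- random_rooted_tree(sample(4:12, 1))
    st <- random_binary_states(phy$tip.label)
    if (all(is.na(st))) st[1] <- 1L
    rec <- fitch_reconstruct(phy, st)
    bf <- brute_force_min_changes(phy, st, alphabet = 0:1)
    expect_equal(rec$cost, bf$cost)
  }
})

test_that("Fitch agrees with an independent parsimony implementation", {
  skip_if_not_installed("phangorn")
  set.seed(303)
  for (i in 1:40) {
    phy <- random_rooted_tree(sample(4:10, 1))
    st <- random_binary_states(phy$tip.label, p_missing = 0)
    rec <- fitch_reconstruct(phy, st)
    dat <- phangorn::phyDat(matrix(as.character(st), ncol = 1,
                                   dimnames = list(names(st), NULL)),
                            type = "USER", levels = c("0", "1"))
    expect_equal(rec$cost, phangorn::parsimony(phy, dat, method = "fitch"))
  }
})

test_that("Dollo places the 7/10 gain on the Xenarthra stem with two losses", {
  rec <- dollo_reconstruct(xtree, character_states(xmatrix, "7/10"), "7/10")
  expect_equal(rec$cost, 3)  # one gain + two losses
  gains <- rec$events[rec$events$type == "gain", ]
  expect_equal(gains$child, "Xenarthra")
  losses <- rec$events[rec$events$type == "loss", ]
  expect_setequal(losses$child, c("CHO", "DNO"))
  expect_equal(rec$node_states$Xenarthra, 1)

  # single present tip: gain on the terminal branch
  st <- setNames(c(1L, rep(0L, 8)), c("BTR", setdiff(xtree$tip.label, "BTR")))
  rec1 <- dollo_reconstruct(xtree, st)
  expect_equal(rec1$cost, 1)
  expect_equal(rec1$events$child, "BTR")
})

test_that("Dollo cost is never below Fitch cost on random characters", {
  set.seed(404)
  for (i in 1:100) {
    phy <- random_rooted_tree(sample(4:10, 1))
    st <- random_binary_states(phy$tip.label)
    if (all(is.na(st) | st == 0, na.rm = TRUE)) next
    f <- fitch_reconstruct(phy, st)
    d <- dollo_reconstruct(phy, st)
    expect_gte(d$cost, f$cost)
    # equality iff some MPR is single-origin
    single_origin <- any(vapply(seq_along(f$mprs), function(i) {
      ev <- f$events[!is.na(f$events$mpr) & f$events$mpr == i, ]
      sum(ev$type == "gain") <= 1 &&
        f$mprs[[i]][[karyoanc:::node_names(phy)[karyoanc:::root_of(phy)]]] == 0
    }, logical(1)))
    if (d$cost == f$cost) expect_true(single_origin || f$cost == 0)
  }
})

test_that("masking a tip never increases the parsimony cost", {
  set.seed(505)
  for (i in 1:60) {
    phy <- random_rooted_tree(sample(4:10, 1))
    st <- random_binary_states(phy$tip.label, p_missing = 0)
    base <- fitch_reconstruct(phy, st)$cost
    st[sample(length(st), 1)] <- NA_integer_
    expect_lte(fitch_reconstruct(phy, st)$cost, base)
  }
})

test_that("Wagner parsimony recovers the published count reconstructions", {
  # HSA 8: three blocks in every resolved xenarthran, two in the outgroup:
  # a single fission step on the Xenarthra stem
  rec <- wagner_counts(xtree, character_states(xmatrix, "HSA8"), "HSA8")
  expect_equal(rec$cost, 1)
  expect_equal(rec$node_states$Xenarthra, 3)
  bf <- brute_force_min_changes(xtree, character_states(xmatrix, "HSA8"))
  expect_equal(rec$cost, bf$cost)
  xen_states <- sort(unique(vapply(bf$assignments, function(a) a[["Xenarthra"]],
                                   integer(1))))
  expect_equal(xen_states, 3L)

  # HSA 6: genuinely ambiguous between one and two ancestral blocks
  rec6 <- wagner_counts(xtree, character_states(xmatrix, "HSA6"), "HSA6")
  expect_setequal(rec6$node_states$Xenarthra, c(1, 2))
  bf6 <- brute_force_min_changes(xtree, character_states(xmatrix, "HSA6"))
  expect_equal(rec6$cost, bf6$cost)
  expect_setequal(unique(vapply(bf6$assignments, function(a) a[["Xenarthra"]],
                                integer(1))), c(1L, 2L))

  # all counts equal: zero cost
  st <- setNames(rep(2L, 9), xtree$tip.label)
  expect_equal(wagner_counts(xtree, st)$cost, 0)

  # ranges are free within their bounds: the B. tridactylus [2,3] tip costs
  # nothing wherever the ancestor sits in the range
  expect_equal(
    wagner_counts(xtree, character_states(xmatrix, "HSA8"))$cost, 1)
})

test_that("Wagner cost equals brute force on random count characters", {
  set.seed(606)
  for (i in 1:100) {
    phy <- random_rooted_tree(sample(4:8, 1))
    st <- random_count_states(phy$tip.label)
    if (all(is.na(st))) next
    rec <- wagner_counts(phy, st)
    bf <- brute_force_min_changes(phy, st)
    expect_equal(rec$cost, bf$cost)
  }
})

test_that("ambiguity resolution honors outgroup tie-breaking and overrides", {
  # 7/10 under Fitch is ambiguous at the Xenarthra node ...
  rec <- fitch_reconstruct(xtree, character_states(xmatrix, "7/10"), "7/10")
  expect_setequal(rec$node_states$Xenarthra, c(0, 1))
  # ... the AEK outgroup alone would resolve it absent ...
  res0 <- resolve_ambiguity(rec, "outgroup", outgroup_state = 0L)
  expect_equal(karyoanc:::resolved_state(res0, "Xenarthra"), 0)
  # ... but the deep-outgroup override resolves it present
  ov <- xen_overrides()[xen_overrides()$character == "7/10", ]
  res1 <- resolve_ambiguity(rec, "outgroup", outgroup_state = 0L, override = ov)
  expect_equal(karyoanc:::resolved_state(res1, "Xenarthra"), 1)
  expect_equal(res1$states$resolved_by[res1$states$node == "Xenarthra"],
               "override")
  # the resolved history gains 7/10 on the Xenarthra stem
  expect_true(any(res1$events$type == "gain" & res1$events$child == "Xenarthra"))

  # unambiguous nodes are untouched no-ops
  rec28 <- fitch_reconstruct(xtree, character_states(xmatrix, "2/8"), "2/8")
  res28 <- resolve_ambiguity(rec28, "outgroup", outgroup_state = 0L)
  expect_equal(karyoanc:::resolved_state(res28, "Xenarthra"), 0)
  expect_equal(res28$states$resolved_by[res28$states$node == "Xenarthra"],
               "unambiguous")

  # policy "report" preserves ambiguity
  resr <- resolve_ambiguity(rec, "report")
  expect_equal(resr$states$state[resr$states$node == "Xenarthra"], "0|1")
  expect_equal(resr$states$resolved_by[resr$states$node == "Xenarthra"],
               "unresolved")

  # an override naming an unknown character errors
  bad <- tibble::tibble(character = "nonexistent", state = 1L, note = "x")
  expect_error(resolve_ambiguity(rec, "outgroup", outgroup_state = 0L,
                                 override = bad), "unknown character")
})

test_that("engines reject malformed input", {
  st <- setNames(c(1L, 0L), c("BTO", "NOT_A_TIP"))
  expect_error(fitch_reconstruct(xtree, st), "missing from states")
  big <- ape::rtree(20)
  expect_error(
    brute_force_min_changes(big, setNames(rep(1L, 20), big$tip.label)),
    "refuses")
})
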