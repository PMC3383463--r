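sim_tree <- read_tree("((A:1,B:1)AB:1,(C:1,D:1)CD:1)SimRoot;")

test_that("zero rates reproduce the ancestor at every tip and at the root", {
  sim <- simulate_karyotypes(sim_config(sim_tree, seed = 5,
                                        fusion_rate = 0, fission_rate = 0))
  for (m in sim$maps) {
    k <- map_to_karyotype(m)
    expect_equal(k$diploid_number, 48)
    d <- compare_karyotypes(k, aek_karyotype())
    expect_equal(nrow(d$associations), 0)
    expect_equal(nrow(d$fragment_counts), 0)
  }
  # reconstruction at the simulated root equals the seeded ancestor
  full_tree <- with_outgroup_tree(sim_tree)
  maps <- c(sim$maps, list(ANC = ancestor_as_map(sim)))
  anc <- infer_ancestral_karyotype(maps, full_tree, "SimRoot",
                                   sim_infer_config())
  d <- compare_karyotypes(anc, aek_karyotype())
  expect_equal(nrow(d$associations), 0)
  expect_equal(nrow(d$fragment_counts), 0)
  expect_equal(anc$diploid_number, 48)
})

test_that("the event algebra holds for every tip in every replicate", {
  for (seed in 1:8) {
    cfg <- sim_config(sim_tree, seed = seed, fusion_rate = 0.4,
                      fission_rate = 0.4)
    sim <- simulate_karyotypes(cfg)
    for (t in names(sim$maps)) {
      ev <- events_on_path(sim, t)
      n_fis <- sum(ev$type == "fission")
      n_fus <- sum(ev$type == "fusion")
      m <- sim$maps[[t]]
      expect_equal(count_segments(m), 31 + n_fis, info = paste(seed, t))
      expect_equal(nrow(m$chromosomes), 24 + n_fis - n_fus,
                   info = paste(seed, t))
      expect_equal(nrow(validate_map(m)), 0, info = paste(seed, t))
    }
  }
})

test_that("identical seeds give identical simulations", {
  cfg <- sim_config(sim_tree, seed = 99, fusion_rate = 0.5, fission_rate = 0.5,
                    probe_failure_prob = 0.2)
  s1 <- simulate_karyotypes(cfg)
  s2 <- simulate_karyotypes(cfg)
  expect_identical(s1$event_log, s2$event_log)
  expect_identical(lapply(s1$maps, tidy), lapply(s2$maps, tidy))
  expect_identical(lapply(s1$maps, function(m) m$probes_failed),
                   lapply(s2$maps, function(m) m$probes_failed))
})

test_that("a fission chain from a single-block ancestor yields 1 + k segments", {
  one <- assemble_karyotype(tibble::tibble(hsa = "1", count = 1L))
  tr <- read_tree("(A:5);")
  for (seed in 1:5) {
    sim <- simulate_karyotypes(sim_config(tr, ancestor = one, seed = seed,
                                          fusion_rate = 0, fission_rate = 0.8))
    k <- sum(sim$event_log$type == "fission")
    expect_equal(count_segments(sim$maps$A), 1 + k)
  }
})

test_that("a single-chromosome ancestor refuses fusions", {
  one <- assemble_karyotype(tibble::tibble(hsa = "1", count = 1L))
  tr <- read_tree("(A:5);")
  sim <- simulate_karyotypes(sim_config(tr, ancestor = one, seed = 3,
                                        fusion_rate = 2, fission_rate = 0))
  expect_equal(nrow(sim$event_log), 0)
  expect_equal(count_segments(sim$maps$A), 1)
})

test_that("probe masking is a no-op at rate 0 and total at rate 1", {
  sim <- simulate_karyotypes(sim_config(sim_tree, seed = 11,
                                        fusion_rate = 0.3, fission_rate = 0.3))
  m0 <- mask_probes(sim$maps, 0, seed = 1)
  expect_identical(lapply(m0, tidy), lapply(sim$maps, tidy))

  m1 <- mask_probes(sim$maps, 1, seed = 1)
  for (m in m1) {
    expect_setequal(setdiff(unique(m$segments$hsa), "X"), character(0))
    expect_length(m$probes_failed, 22)
  }
  # a fully masked matrix scores every autosomal character missing
  mm <- build_character_matrix(m1, "missing")
  aut <- mm |> dplyr::filter(character != "HSAX")
  expect_true(all(aut$status == "missing"))
})

test_that("a single-probe mask turns its associations uncertain, as with the failed HSA 21 probe", {
  sim <- simulate_karyotypes(sim_config(sim_tree, seed = 2,
                                        fusion_rate = 0, fission_rate = 0))
  m <- sim$maps$A
  # drop the HSA 21 probe by hand: the 3/21 chromosome keeps only HSA 3
  seg <- dplyr::filter(m$segments, hsa != "21")
  masked <- painting_map(seg, m$chromosomes, taxon = "A",
                         probes_failed = "21",
                         diploid_number_reported = m$diploid_number_reported)
  mm <- build_character_matrix(list(A = masked, B = sim$maps$B), "missing")
  row <- mm |> dplyr::filter(taxon == "A", character == "3/21")
  expect_equal(row$status, "missing")
  row21 <- mm |> dplyr::filter(taxon == "A", character == "HSA21")
  expect_equal(row21$status, "missing")
})

test_that("root recovery degrades monotonically with event rate and is high at low rates", {
  rates <- c(0, 0.15, 0.6)
  full_tree <- with_outgroup_tree(sim_tree)
  f1_at <- function(rate, seeds) {
    mean(vapply(seeds, function(s) {
      sim <- simulate_karyotypes(sim_config(sim_tree, seed = s,
                                            fusion_rate = rate,
                                            fission_rate = rate))
      maps <- c(sim$maps, list(ANC = ancestor_as_map(sim)))
      anc <- infer_ancestral_karyotype(maps, full_tree, "SimRoot",
                                       sim_infer_config())
      truth <- karyotype_associations(aek_karyotype())
      got <- karyotype_associations(anc)
      tp <- sum(pmin(truth$multiplicity[match(got$association, truth$association)],
                     got$multiplicity), na.rm = TRUE)
      prec <- if (sum(got$multiplicity) == 0) 1 else tp / sum(got$multiplicity)
      rec <- tp / sum(truth$multiplicity)
      if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    }, numeric(1)))
  }
  f1 <- vapply(rates, f1_at, numeric(1), seeds = 1:12)
  expect_equal(f1[1], 1)
  expect_true(all(diff(f1) <= 1e-9))
  # frozen calibration threshold at the default low rate (see vignette)
  expect_gte(f1_at(0.1, seeds = 1:50), 0.95)
})
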