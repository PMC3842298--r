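# Pad construction: layout, attachment topology, pool counts and the
# configuration-dependent synapse lists.

test_that("the pad has the 4/4/7/7/7 whisker layout", {
  lay <- pad_layout()
  expect_equal(nrow(lay), 29)
  expect_equal(unname(table(lay$row)[c("A", "B", "C", "D", "E")]),
               c(4L, 4L, 7L, 7L, 7L), ignore_attr = TRUE)
})

test_that("total first-order afferent count is 29 whiskers x 162 cells", {
  net <- build_network(whisk_configuration("CPG_ONLY", "NONE", seed = 1))
  counts <- network_counts(net)
  expect_equal(counts$count[counts$component == "sn1"], 29 * 162)
  expect_equal(sum(net$sn1_n), 162)
  expect_equal(unname(net$sn1_n[c("D", "W", "C", "P")]), c(28, 73, 33, 28))
})

test_that("muscle attachments follow the pad anatomy", {
  net <- build_network(whisk_configuration("CPG_ONLY", "NONE", seed = 1))
  W <- net$attach
  lay <- net$layout
  types <- net$muscles$type[match(colnames(W), net$muscles$muscle)]
  for (i in seq_len(nrow(lay))) {
    att <- W[i, ] != 0
    # every whisker: >= 1 intrinsic, an extP group, and both retractor layers
    expect_gte(sum(att & types == "intrinsic"), 1)
    expect_equal(sum(att & types == "extP"), 1)
    expect_equal(sum(att & types == "extR_sup"), 1)
    expect_equal(sum(att & types == "extR_deep"), 1)
  }
  # rostral-most C-E: exactly one intrinsic, no pseudo-intrinsic
  for (w in rostral_ce()) {
    i <- match(w, lay$whisker)
    expect_equal(sum(W[i, ] != 0 & types == "intrinsic"), 1)
    expect_equal(sum(W[i, ] != 0 & types == "pseudo_intrinsic"), 0)
  }
  # rostral-most A-B carry the pseudo-intrinsic instead
  for (w in c("A4", "B4")) {
    i <- match(w, lay$whisker)
    expect_equal(sum(W[i, ] != 0 & types == "pseudo_intrinsic"), 1)
  }
  # other whiskers are slung by two intrinsic muscles
  expect_equal(sum(W[match("C3", lay$whisker), ] != 0 & types == "intrinsic"), 2)
})

test_that("rebuilding with the same seed reproduces the identical wiring", {
  h1 <- whiskloop:::network_hash(
    build_network(whisk_configuration("CPG_ONLY", "E_R", seed = 5)))
  h2 <- whiskloop:::network_hash(
    build_network(whisk_configuration("CPG_ONLY", "E_R", seed = 5)))
  h3 <- whiskloop:::network_hash(
    build_network(whisk_configuration("CPG_ONLY", "E_R", seed = 6)))
  expect_identical(h1, h2)
  expect_false(identical(h1, h3))
})

test_that("graph sanity: subtype separation and motoneuron targets", {
  net <- build_network(whisk_configuration("CPG_ONLY", "NONE", seed = 1))
  syn <- net$synapses
  ss <- syn[syn$kind == "sn1_sn2", ]
  pre_sub <- sub("^sn1_([A-Z])_.*$", "\\1", ss$pre)
  post_sub <- sub("^sn2_([A-Z])_.*$", "\\1", ss$post)
  expect_true(all(pre_sub == post_sub))  # no cross-subtype edges
  # and no cross-whisker afferent edges: separated per-whisker loops
  pre_w <- sub("^sn1_[A-Z]_([A-E][0-9]+)#.*$", "\\1", ss$pre)
  post_w <- sub("^sn2_[A-Z]_([A-E][0-9]+)#.*$", "\\1", ss$post)
  expect_true(all(pre_w == post_w))
  # every motoneuron pool innervates at least one muscle
  mm <- syn[syn$kind == "mn_muscle", ]
  all_mn <- paste0("mn_", rep(c("Int", "ExtP", "ExtR"), each = 29), "_",
                   rep(net$layout$whisker, times = 3))
  expect_setequal(unique(mm$pre), all_mn)
})

test_that("the TIP axis wires the configured feedback and nothing else", {
  syn_of <- function(tipm, wm = "CPG_ONLY") {
    build_network(whisk_configuration(wm, tipm, seed = 1))$synapses
  }
  s0 <- syn_of("NONE")
  expect_equal(sum(s0$kind == "tip"), 0)
  expect_equal(sum(s0$kind == "sn2w_mn"), 0)   # open loop: no SN2 -> MN

  er <- syn_of("E_R"); er_t <- er[er$kind == "tip", ]
  expect_true(all(er_t$sign == "+"))
  expect_true(all(grepl("^mn_ExtR_", er_t$post)))
  # per-whisker loop: the touching whisker's feedback targets its own pool
  expect_true(all(sub("^sn2_[CP]_", "", er_t$pre) ==
                    sub("^mn_ExtR_", "", er_t$post)))
  expect_setequal(sub("^sn2_", "", sub("_[A-E][0-9]+$", "", er_t$pre)),
                  c("C", "P"))  # contact + pressure cells only, no detach

  di <- syn_of("DIRECT_I_P"); di_t <- di[di$kind == "tip", ]
  expect_true(all(di_t$sign == "-"))
  expect_true(all(grepl("^mn_Int_", di_t$post)))

  ind <- syn_of("INDIRECT_I_P"); ind_t <- ind[ind$kind == "tip", ]
  expect_true(all(ind_t$sign == "-"))
  expect_true(all(ind_t$post == "cpg_Int"))

  so <- syn_of("NONE", "SENSORY_ONLY")
  expect_equal(sum(so$kind == "cpg_mn"), 0)
  expect_gt(sum(so$kind == "sn2w_mn"), 0)
})

test_that("a network description exports as parseable JSON", {
  net <- build_network(whisk_configuration("CPG_ONLY", "E_R", seed = 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(js$configuration$tip_mechanism, "E_R")
  expect_equal(length(js$components$whiskers), 29)
  expect_gt(nrow(js$synapses), 1000)
})

test_that("configuration validation rejects bad values", {
  expect_error(whisk_configuration("CPG_MAYBE"), "arg")
  expect_error(whisk_configuration(tip_mechanism = "E_P"), "arg")
  expect_error(whisk_configuration(seed = NA), "seed")
})
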