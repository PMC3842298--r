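# Construction of the modelled mystacial pad: the 4/4/7/7/7 whisker array,
# the intrinsic / pseudo-intrinsic / extrinsic muscle attachment topology,
# per-whisker afferent and motoneuron pools, and the synaptic wiring implied
# by a run configuration (whisking mechanism x TIP mechanism).

WHISKING_MECHANISMS <- c("CPG_ONLY", "SENSORY_ONLY", "CPG_PLUS_SENSORY")
TIP_MECHANISMS <- c("NONE", "E_R", "DIRECT_I_P", "INDIRECT_I_P")
MN_TYPES <- c("Int", "ExtP", "ExtR")
SN_SUBTYPES <- c("W", "C", "P", "D")

#' Mystacial pad layout
#'
#' Five rows of ipsilateral whiskers: rows A and B with four whiskers, rows
#' C, D and E with seven. Whiskers are indexed caudal (1) to rostral within
#' each row.
#'
#' @return tibble with one row per whisker: `whisker` (e.g. `"C2"`), `row`,
#'   `arc`, `idx` (1..29), `group` (`"AB"` or `"CE"`, the extrinsic
#'   deep-muscle grouping), `n_row`, and `rostral_most`.
#' @export
pad_layout <- function() {
  rows <- c(A = 4L, B = 4L, C = 7L, D = 7L, E = 7L)
  out <- purrr::imap_dfr(as.list(rows), function(n, r) {
    tibble::tibble(row = r, arc = seq_len(n), n_row = n)
  })
  out$whisker <- paste0(out$row, out$arc)
  out$idx <- seq_len(nrow(out))
  out$group <- ifelse(out$row %in% c("A", "B"), "AB", "CE")
  out$rostral_most <- out$arc == out$n_row
  out[, c("whisker", "row", "arc", "idx", "group", "n_row", "rostral_most")]
}

#' Run configuration
#'
#' @param whisking_mechanism one of `"CPG_ONLY"`, `"SENSORY_ONLY"`,
#'   `"CPG_PLUS_SENSORY"`: which pre-synaptic sources drive the motoneurons
#'   during free-air whisking, and the matching threshold regime.
#' @param tip_mechanism one of `"NONE"`, `"E_R"` (touch feedback excites
#'   extrinsic-retractor motoneurons), `"DIRECT_I_P"` (touch feedback
#'   inhibits the touching whisker's intrinsic motoneurons), or
#'   `"INDIRECT_I_P"` (touch feedback inhibits the intrinsic CPG).
#' @param seed integer seed; fixes the afferent fan-in draw and all other
#'   randomness, making runs exactly reproducible.
#' @param overrides parameter overrides, see [whisk_params()].
#' @return a `whisk_configuration` list.
#' @export
whisk_configuration <- function(whisking_mechanism = "CPG_ONLY",
                                tip_mechanism = "NONE",
                                seed = 1L,
                                overrides = NULL) {
  whisking_mechanism <- match.arg(whisking_mechanism, WHISKING_MECHANISMS)
  tip_mechanism <- match.arg(tip_mechanism, TIP_MECHANISMS)
  if (is.null(seed) || is.na(seed)) stop("seed is mandatory", call. = FALSE)
  structure(list(whisking_mechanism = whisking_mechanism,
                 tip_mechanism = tip_mechanism,
                 seed = as.integer(seed),
                 overrides = overrides),
            class = "whisk_configuration")
}

# Muscle table + signed whisker attachment weights.
# Intrinsic muscle i of a row connects follicles (i-1, i): it protracts
# whisker i-1 at full weight and whisker i at the reduced rostral share s;
# muscle 1 is pad-anchored and drives only whisker 1 (at s). Every whisker is
# thus slung by two intrinsic muscles except the rostral-most, which keeps
# only its caudal one; in rows A-B that missing rostral muscle is replaced by
# a pseudo-intrinsic protractor, in rows C-E it is simply absent (which is
# what caps the rostral-most C-E protraction peak).
build_muscles <- function(layout, p) {
  s <- p$muscle$share_rostral
  mus <- list()
  att <- list()  # per muscle: tibble(whisker idx, weight signed)
  for (r in unique(layout$row)) {
    wr <- layout[layout$row == r, ]
    n <- wr$n_row[1]
    for (i in seq_len(n)) {
      id <- paste0("int_", r, i)
      rows <- tibble::tibble(idx = integer(), w = numeric())
      if (i > 1) rows <- tibble::add_row(rows, idx = wr$idx[i - 1], w = 1)
      rows <- tibble::add_row(rows, idx = wr$idx[i], w = s)
      mus[[id]] <- list(id = id, type = "intrinsic", row = r, group = wr$group[1])
      att[[id]] <- rows
    }
    if (wr$group[1] == "AB") {
      id <- paste0("pi_", r)
      mus[[id]] <- list(id = id, type = "pseudo_intrinsic", row = r, group = "AB")
      att[[id]] <- tibble::tibble(idx = wr$idx[n], w = 1)
    }
  }
  for (g in c("AB", "CE")) {
    id <- paste0("extP_", g)
    mus[[id]] <- list(id = id, type = "extP", row = NA, group = g)
    att[[id]] <- tibble::tibble(idx = layout$idx[layout$group == g], w = 1)
  }
  mus[["extR_sup"]] <- list(id = "extR_sup", type = "extR_sup", row = NA,
                            group = "ALL")
  att[["extR_sup"]] <- tibble::tibble(idx = layout$idx, w = -1)
  for (g in c("AB", "CE")) {
    id <- paste0("extR_deep_", g)
    mus[[id]] <- list(id = id, type = "extR_deep", row = NA, group = g)
    att[[id]] <- tibble::tibble(idx = layout$idx[layout$group == g], w = -1)
  }
  ids <- names(mus)
  W <- matrix(0, nrow = nrow(layout), ncol = length(ids),
              dimnames = list(layout$whisker, ids))
  for (id in ids) W[att[[id]]$idx, id] <- att[[id]]$w
  tab <- tibble::tibble(
    muscle = ids,
    type = vapply(mus, `[[`, "", "type"),
    row = vapply(mus, function(m) as.character(m$row %||% NA), ""),
    group = vapply(mus, `[[`, "", "group")
  )
  list(table = tab, attach = W)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Which Int_MN pools innervate an intrinsic muscle: the pools of the whiskers
# it is attached to. Extrinsic group muscles are innervated by every matching
# pool in their group.
build_innervation <- function(layout, muscles) {
  W <- muscles$attach
  tab <- muscles$table
  inner <- list()
  for (j in seq_len(nrow(tab))) {
    id <- tab$muscle[j]
    wids <- rownames(W)[W[, id] != 0]
    type <- switch(tab$type[j],
                   intrinsic = "Int", pseudo_intrinsic = "Int",
                   extP = "ExtP", extR_sup = "ExtR", extR_deep = "ExtR")
    inner[[id]] <- list(mn_type = type, whiskers = wids)
  }
  inner
}

#' Build the wired pad network for a configuration
#'
#' Deterministic given the configuration's seed. Base wiring: per whisker and
#' afferent subtype, each second-order cell draws a random 50% of that
#' subtype's first-order pool (without replacement); each CPG innervates all
#' motoneurons of its type; each motoneuron pool innervates the muscles of
#' its type attached to its whisker. The TIP axis adds contact/pressure
#' feedback onto retractor motoneurons (`E_R`), the touching whisker's
#' intrinsic motoneurons (`DIRECT_I_P`, inhibitory) or the intrinsic CPG
#' (`INDIRECT_I_P`, inhibitory); the whisking axis selects which of
#' {CPG, SN2_W} innervate the motoneurons and the threshold regime.
#'
#' @param configuration a [whisk_configuration()].
#' @return a `whisk_network` list: `layout`, `muscles`, `attach` (signed
#'   whisker-by-muscle torque weights), `innervation`, `pools`, `fanin`
#'   (per whisker and subtype, SN2-by-SN1 0/1 matrices), `synapses` tibble,
#'   `params`, `config`.
#' @export
build_network <- function(configuration) {
  stopifnot(inherits(configuration, "whisk_configuration"))
  p <- whisk_params(configuration$overrides)
  errs <- validate_params(p)
  if (length(errs)) stop("invalid parameters: ", paste(errs, collapse = "; "),
                         call. = FALSE)
  layout <- pad_layout()
  muscles <- build_muscles(layout, p)
  innervation <- build_innervation(layout, muscles)

  sn1_n <- c(W = p$pools$sn1_w, C = p$pools$sn1_c, P = p$pools$sn1_p,
             D = p$pools$sn1_d)
  n_sn2 <- p$pools$sn2_per_subtype
  n_mn <- p$pools$mn_per_type

  fanin <- list()
  w_offsets <- list()
  withr::with_seed(configuration$seed, {
    for (w in layout$whisker) {
      fw <- list()
      for (st in SN_SUBTYPES) {
        k <- round(p$pools$sn2_fanin_frac * sn1_n[[st]])
        M <- matrix(0L, nrow = n_sn2, ncol = sn1_n[[st]])
        for (i in seq_len(n_sn2)) M[i, sample.int(sn1_n[[st]], k)] <- 1L
        fw[[st]] <- M
      }
      fanin[[w]] <- fw
      w_offsets[[w]] <- stats::runif(sn1_n[["W"]], 0, p$afferent$w_interval_ms)
    }
  })
  # spontaneous whisking-afferent phases share the seeded draw
  w_spont_offsets <- list()
  withr::with_seed(configuration$seed + 1L, {
    for (w in layout$whisker) {
      w_spont_offsets[[w]] <- stats::runif(sn1_n[["W"]], 0,
                                           1000 / p$afferent$w_spont_hz)
    }
  })

  syn <- build_synapses(layout, innervation, fanin, configuration, p,
                        sn1_n, n_sn2, n_mn)

  net <- list(layout = layout,
              muscles = muscles$table,
              attach = muscles$attach,
              innervation = innervation,
              sn1_n = sn1_n, n_sn2 = n_sn2, n_mn = n_mn,
              fanin = fanin, w_offsets = w_offsets,
              w_spont_offsets = w_spont_offsets,
              synapses = syn,
              params = p,
              config = configuration)
  class(net) <- "whisk_network"
  net
}

build_synapses <- function(layout, innervation, fanin, cfg, p,
                           sn1_n, n_sn2, n_mn) {
  rowsl <- list()
  add <- function(pre, post, weight, sign, kind) {
    rowsl[[length(rowsl) + 1L]] <<- tibble::tibble(
      pre = pre, post = post, weight = weight, sign = sign, kind = kind)
  }
  pool_id <- function(prefix, tag, w) paste0(prefix, "_", tag, "_", w)

  for (w in layout$whisker) {
    for (st in SN_SUBTYPES) {
      M <- fanin[[w]][[st]]
      pre_cells <- which(M == 1L, arr.ind = TRUE)
      add(paste0(pool_id("sn1", st, w), "#", pre_cells[, "col"]),
          paste0(pool_id("sn2", st, w), "#", pre_cells[, "row"]),
          1, "+", "sn1_sn2")
    }
  }
  for (ty in MN_TYPES) {
    if (cfg$whisking_mechanism != "SENSORY_ONLY") {
      w_cpg <- if (cfg$whisking_mechanism == "CPG_ONLY") p$neuron$w_cpg_solo
               else p$neuron$w_cpg_coinc
      add(paste0("cpg_", ty), pool_id("mn", ty, layout$whisker), w_cpg, "+",
          "cpg_mn")
    }
  }
  if (cfg$whisking_mechanism != "CPG_ONLY") {
    w_sn2w <- if (cfg$whisking_mechanism == "SENSORY_ONLY") p$neuron$w_sn2w_solo
              else p$neuron$w_sn2w_coinc
    for (w in layout$whisker) {
      for (ty in MN_TYPES) {
        add(pool_id("sn2", "W", w), pool_id("mn", ty, w), w_sn2w, "+", "sn2w_mn")
      }
    }
  }
  for (id in names(innervation)) {
    inn <- innervation[[id]]
    add(pool_id("mn", inn$mn_type, inn$whiskers), id, 1, "+", "mn_muscle")
  }
  if (cfg$tip_mechanism == "E_R") {
    for (w in layout$whisker) {
      add(pool_id("sn2", c("C", "P"), w), pool_id("mn", "ExtR", w),
          p$neuron$tip_w, "+", "tip")
    }
  } else if (cfg$tip_mechanism == "DIRECT_I_P") {
    for (w in layout$whisker) {
      add(pool_id("sn2", c("C", "P"), w), pool_id("mn", "Int", w),
          p$neuron$tip_w, "-", "tip")
    }
  } else if (cfg$tip_mechanism == "INDIRECT_I_P") {
    for (w in layout$whisker) {
      add(pool_id("sn2", c("C", "P"), w), "cpg_Int", p$neuron$tip_w, "-", "tip")
    }
  }
  dplyr::bind_rows(rowsl)
}

#' Summarise or export a network description
#'
#' Writes components, synapses and muscle groups as JSON for inspection and
#' diffing between configurations.
#'
#' @param net a `whisk_network`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(net, path) {
  comp <- list(
    whiskers = net$layout$whisker,
    cpgs = paste0("cpg_", MN_TYPES),
    muscles = as.list(stats::setNames(net$muscles$type, net$muscles$muscle)),
    pools = list(sn1 = as.list(net$sn1_n), sn2_per_subtype = net$n_sn2,
                 mn_per_type = net$n_mn)
  )
  out <- list(configuration = unclass(net$config)[c("whisking_mechanism",
                                                    "tip_mechanism", "seed")],
              components = comp,
              synapses = net$synapses,
              groups = split(net$muscles$muscle, net$muscles$group))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Total neuron and component counts of a network
#'
#' @param net a `whisk_network`.
#' @return tibble of component counts (one row per class), including the
#'   per-pad totals: 29 whiskers x 162 first-order afferents = 4698 SN1s.
#' @export
network_counts <- function(net) {
  nw <- nrow(net$layout)
  tibble::tibble(
    component = c("whisker", "muscle", "cpg", "sn1", "sn2", "mn"),
    count = c(nw, nrow(net$muscles), 3L,
              nw * sum(net$sn1_n),
              nw * net$n_sn2 * length(SN_SUBTYPES),
              nw * net$n_mn * length(MN_TYPES))
  )
}

# Stable hash of the wiring (synapse list + fan-in draws): used to assert
# that rebuilding with the same seed reproduces the identical network.
network_hash <- function(net) {
  tmp <- tempfile(fileext = ".bin")
  on.exit(unlink(tmp))
  payload <- list(syn = as.data.frame(net$synapses), fanin = net$fanin,
                  w_offsets = net$w_offsets,
                  w_spont_offsets = net$w_spont_offsets)
  saveRDS(payload, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}
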