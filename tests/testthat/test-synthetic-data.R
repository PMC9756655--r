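test_that("generation is deterministic given the seed", {
  cfg <- synthetic_config(n_genera_per_order = 2, n_genomes_per_genus = 2,
                          replicon_length_bp = 5e4, emit_sequences = TRUE,
                          seed = 7)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_dataset(cfg, out_dir = d1)
  generate_dataset(cfg, out_dir = d2)
  files <- list.files(d1, recursive = TRUE)
  expect_true(length(files) > 5)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  generate_dataset(synthetic_config(n_genera_per_order = 2,
                                    n_genomes_per_genus = 2,
                                    replicon_length_bp = 5e4,
                                    emit_sequences = TRUE, seed = 8),
                   out_dir = d3)
  expect_false(identical(readLines(file.path(d1, "domain_hits.tsv")),
                         readLines(file.path(d3, "domain_hits.tsv"))))
})

test_that("pipeline classification recovers planted class counts exactly", {
  for (seed in c(1, 2, 3)) {
    cfg <- synthetic_config(n_genera_per_order = 3, n_genomes_per_genus = 2,
                            replicon_length_bp = 3e5, seed = seed)
    ds <- generate_dataset(cfg)
    counts <- classify_genomes(ds$genomes)$counts
    m <- merge(counts, ds$truth$planted_counts, by = "genome_id",
               suffixes = c(".obs", ".true"))
    for (k in CDG_CLASSES)
      expect_equal(m[[paste0(k, ".obs")]], m[[paste0(k, ".true")]],
                   label = paste("class", k, "seed", seed))
  }
})

test_that("emitted files reproduce the in-memory dataset", {
  cfg <- synthetic_config(n_genera_per_order = 2, n_genomes_per_genus = 2,
                          replicon_length_bp = 1e5, emit_sequences = TRUE,
                          seed = 5)
  dir <- withr::local_tempdir()
  ds <- generate_dataset(cfg, out_dir = dir)
  ld <- load_dataset(dir)
  expect_equal(sort(names(ld$genomes)), sort(names(ds$genomes)))
  c1 <- classify_genomes(ds$genomes)$counts
  c2 <- classify_genomes(ld$genomes)$counts
  m <- merge(c1, c2, by = "genome_id", suffixes = c(".mem", ".file"))
  for (k in CDG_CLASSES)
    expect_equal(m[[paste0(k, ".mem")]], m[[paste0(k, ".file")]])
  # gene loci survive the GFF3 round trip
  g <- ds$genomes[[1]]; h <- ld$genomes[[g$genome_id]]
  ord1 <- order(g$proteins$protein_id); ord2 <- order(h$proteins$protein_id)
  expect_equal(h$proteins$start[ord2], g$proteins$start[ord1])
  expect_equal(h$proteins$end[ord2], g$proteins$end[ord1])
})

test_that("planted positional model is recovered end to end", {
  # EAL genes planted as a wrapped normal near ori must yield a KDE argmax
  # near the planted mode after nt placement and back-conversion
  cfg <- synthetic_config(n_orders = 1, n_genera_per_order = 10,
                          n_genomes_per_genus = 10,
                          replicon_length_bp = 3e5,
                          class_count_means = c(GGDEF = 0, EAL = 3,
                                                GGDEF_EAL = 0, HD_GYP = 0),
                          seed = 9)
  ds <- generate_dataset(cfg)
  cls <- classify_genomes(ds$genomes)$classified
  pos <- normalized_positions_table(cls, ds$genomes, ds$ori_table)$positions
  expect_gt(nrow(pos), 150)
  de <- kde_circular(pos$position[pos$class == "EAL"])
  argmax <- de$grid[which.max(de$density)]
  dist0 <- min(abs(argmax - 5), 100 - abs(argmax - 5))
  expect_lt(dist0, 3)
  # and the emitted positions match the sampled truth per gene
  tr <- ds$truth$genes[ds$truth$genes$true_class == "EAL", ]
  m <- merge(pos, tr, by = "protein_id")
  dd <- abs(m$position - m$true_position)
  expect_lt(max(pmin(dd, 100 - dd)), 1.5)  # nt rounding + overlap shifts
})

test_that("HD decoys carry no motif and HD-GYP proteins always do", {
  cfg <- synthetic_config(n_genera_per_order = 4, n_genomes_per_genus = 3,
                          replicon_length_bp = 3e5, motif_rate = 0.5,
                          class_count_means = c(GGDEF = 1, EAL = 1,
                                                GGDEF_EAL = 1, HD_GYP = 3),
                          seed = 13)
  ds <- generate_dataset(cfg)
  cls <- do.call(rbind, lapply(ds$genomes, function(g) {
    cg <- classify_genome(g)$classified
    cg$sequence <- g$proteins$sequence[match(cg$protein_id,
                                             g$proteins$protein_id)]
    cg
  }))
  hd_gyp <- cls[cls$class == "HD_GYP", ]
  expect_gt(nrow(hd_gyp), 0)
  expect_true(all(grepl("HHE.{5}GYP", hd_gyp$sequence)))
  decoys <- cls[cls$class == "NONE" & cls$cdg_domains == "", ]
  expect_gt(nrow(decoys), 0)
  expect_false(any(grepl("HHE.{5}GYP", decoys$sequence)))
  # truth record agrees
  m <- merge(cls, ds$truth$genes, by = "protein_id")
  expect_equal(m$class, m$true_class)
})

test_that("default profile plants separable GGDEF/EAL position models", {
  cfg <- default_paper_profile(seed = 3)
  for (k in CDG_CLASSES)
    expect_equal(sum(cfg$position_model[[k]]$weight), 1)
  set.seed(33)
  x <- sample_positions(cfg, "GGDEF", 150)
  y <- sample_positions(cfg, "EAL", 150)
  expect_true(all(x >= 0 & x < 100))
  expect_lt(ks_two_sample(x, y)$p_value, 0.05)
  # mean-count ratio planted at 2
  expect_equal(unname(cfg$class_count_means["GGDEF"] /
                        cfg$class_count_means["EAL"]), 2)
})

test_that("infeasible configurations abort rather than truncate", {
  cfg <- synthetic_config(n_genera_per_order = 1, n_genomes_per_genus = 1,
                          replicon_length_bp = 1.2e4,
                          class_count_means = c(GGDEF = 30, EAL = 10,
                                                GGDEF_EAL = 5, HD_GYP = 2),
                          secondary_chromosome_prob = 0, seed = 17)
  expect_error(generate_dataset(cfg), "infeasible")
})
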