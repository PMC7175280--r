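test_that("FO replaces every codon with the host family maximum", {
  ec <- ecoli_tab()
  set.seed(11)
  gene <- random_gene(40)
  res <- harmonize_fo(gene, ec)
  sense <- res$ledger$amino_acid != "*"
  expect_true(all(res$ledger$host_rcu[sense] == 100))
  expect_equal(arcu(res$sequence, ec), 100)
  expect_identical(translate_cds(res$sequence), translate_cds(gene))
  # Met can only ever be ATG
  expect_true(all(res$ledger$chosen_codon[res$ledger$amino_acid == "M"]
                  == "ATG"))
})

test_that("DO reproduces the documented leucine substitutions", {
  mm <- mouse_tab()
  ec <- ecoli_tab()
  res <- harmonize_do("ATGCTTCTCTAA", mm, ec)
  led <- res$ledger
  # native CTT at 33% picks the host codon at 34% (TTG)
  expect_equal(led$native_rcu[2], 33)
  expect_identical(led$chosen_codon[2], "TTG")
  expect_equal(led$host_rcu[2], 34)
  # native CTC: CTT (>5 points below) is excluded, TTA is chosen
  expect_identical(led$chosen_codon[3], "TTA")
  expect_false(grepl("CTT", led$feasible_set[3]))
  # terminal stop passes through untouched
  expect_identical(led$chosen_codon[4], "TAA")
  expect_match(led$rule_note[4], "stop-preserved")
})

test_that("DO floor holds and native maxima force the host maximum", {
  mm <- mouse_tab()
  ec <- ecoli_tab()
  set.seed(5)
  for (rep in 1:20) {
    gene <- random_gene(30)
    res <- harmonize_do(gene, mm, ec)
    sense <- res$ledger$amino_acid != "*"
    expect_true(all(res$ledger$host_rcu[sense] >=
                      res$ledger$native_rcu[sense] - 5))
  }
  # a gene written in native family-max codons optimizes fully
  aas <- c("M", "L", "A", "G", "K", "V", "R", "S", "T", "P")
  maxgene <- paste(vapply(aas, function(a)
    family_extreme_codon(mm, a, "max"), character(1)), collapse = "")
  expect_identical(harmonize_do(maxgene, mm, ec)$sequence,
                   harmonize_fo(maxgene, ec)$sequence)
})

test_that("NT picks the closest host codon from below, with fallback", {
  # host Ala rcus {100, 34, 31, 11}; native codon at 33 -> 31 chosen
  host <- toy_table(c(GCT = 100, GCC = 34, GCA = 31, GCG = 11), "host")
  native <- toy_table(c(GCT = 100, GCC = 33, GCA = 50, GCG = 5), "native")
  res <- harmonize_nt("ATGGCC", native, host)
  expect_identical(res$ledger$chosen_codon[2], "GCA")
  expect_equal(res$ledger$host_rcu[2], 31)
  expect_identical(res$ledger$rule_note[2], "nt")
  # native at 5 sits below every host synonym: minimal host rcu, noted
  host2 <- toy_table(c(GCT = 100, GCC = 30, GCA = 10, GCG = 10), "host2")
  res2 <- harmonize_nt("ATGGCG", native, host2)
  expect_equal(res2$ledger$host_rcu[2], 10)
  expect_identical(res2$ledger$rule_note[2], "nt-fallback")
  # native maximum maps to the host maximum
  res3 <- harmonize_nt("ATGGCT", native, host)
  expect_equal(res3$ledger$host_rcu[2], 100)
})

test_that("NT ceiling holds on every non-fallback ledger row", {
  mm <- mouse_tab()
  ec <- ecoli_tab()
  set.seed(6)
  for (rep in 1:20) {
    res <- harmonize_nt(random_gene(30), mm, ec)
    led <- res$ledger[res$ledger$rule_note == "nt", ]
    expect_true(all(led$host_rcu <= led$native_rcu))
  }
})

test_that("LSR distribution follows the clamped-linear score", {
  one <- compute_lsr(50, data.frame(codon = "CTG", host_rcu = 10))
  expect_equal(one$lsr, 1)
  two <- compute_lsr(50, data.frame(codon = c("A1", "A2"),
                                    host_rcu = c(50, 100)))
  expect_equal(two$lsr, c(100 / 150, 50 / 150))
  expect_equal(sum(two$lsr), 1, tolerance = 1e-9)
  # all candidates equidistant -> uniform
  uni <- compute_lsr(50, data.frame(codon = c("A1", "A2", "A3"),
                                    host_rcu = c(40, 60, 40)))
  expect_equal(uni$lsr, rep(1 / 3, 3))
  # lsr is non-increasing in the absolute delta
  ec <- ecoli_tab()
  lt <- compute_lsr(33, data.frame(codon = codon_families()$L,
                                   host_rcu = unname(ec$rcu[codon_families()$L])))
  expect_true(all(diff(lt$lsr) <= 1e-12))
  expect_true(all(diff(lt$abs_delta) >= -1e-12))
})

test_that("the FT cumulative walk selects by accumulated LSR", {
  lt <- data.frame(codon = c("AAA", "AAG"), host_rcu = c(50, 10),
                   abs_delta = c(0, 40), lsr = c(0.8, 0.2))
  expect_identical(codonharmony:::lsr_select(lt, 0.5)$codon, "AAA")
  expect_identical(codonharmony:::lsr_select(lt, 0.9)$codon, "AAG")
  expect_identical(codonharmony:::lsr_select(lt, 0.999999)$codon, "AAG")
})

test_that("FT is seed-reproducible and seed-sensitive", {
  mm <- mouse_tab()
  ec <- ecoli_tab()
  set.seed(42)
  gene <- random_gene(120)
  a <- harmonize_ft(gene, mm, ec, harmonization_config(ft_seed = 7))
  b <- harmonize_ft(gene, mm, ec, harmonization_config(ft_seed = 7))
  c <- harmonize_ft(gene, mm, ec, harmonization_config(ft_seed = 8))
  expect_identical(a$sequence, b$sequence)
  expect_false(identical(a$sequence, c$sequence))
  # Met/Trp positions are invariant under any seed
  mw <- a$ledger$amino_acid %in% c("M", "W")
  expect_identical(a$ledger$chosen_codon[mw], c$ledger$chosen_codon[mw])
  expect_error(harmonize_ft(gene, mm, ec,
                            harmonization_config(ft_seed = NULL)),
               "ft_seed")
})

test_that("all four engines preserve the translation", {
  mm <- mouse_tab()
  bx <- burk_tab()
  ec <- ecoli_tab()
  rmap <- region_map(data.frame(start = c(1, 16), end = c(15, 40),
                                table_id = c("mouse", "burk")),
                     tables = list(mouse = mm, burk = bx))
  set.seed(9)
  for (rep in 1:10) {
    gene <- random_gene(40)
    prot <- translate_cds(gene)
    expect_identical(translate_cds(harmonize_fo(gene, ec)$sequence), prot)
    expect_identical(translate_cds(harmonize_do(gene, rmap, ec)$sequence),
                     prot)
    expect_identical(translate_cds(harmonize_nt(gene, rmap, ec)$sequence),
                     prot)
    expect_identical(translate_cds(
      harmonize_ft(gene, rmap, ec,
                   harmonization_config(ft_seed = rep))$sequence), prot)
  }
})

test_that("internal stop codons abort with the offending position", {
  ec <- ecoli_tab()
  expect_error(harmonize_fo("ATGTAAAAATAA", ec), "codon position 2")
  expect_error(harmonize_fo("ATGAA", ec), "divisible by 3")
})

test_that("region maps validate coverage and feed per-segment tables", {
  mm <- mouse_tab()
  bx <- burk_tab()
  ec <- ecoli_tab()
  expect_error(region_map(data.frame(start = c(1, 10), end = c(5, 20),
                                     table_id = c("a", "b")),
                          tables = list(a = mm, b = bx)),
               "contiguous")
  expect_error(region_map(data.frame(start = 1, end = 5, table_id = "zz"),
                          tables = list(a = mm)), "unresolvable")
  rmap <- region_map(data.frame(start = c(1, 3), end = c(2, 4),
                                table_id = c("mouse", "burk")),
                     tables = list(mouse = mm, burk = bx))
  # CTT scores 33 in the mouse-like segment but differently in the
  # Burkholderia-like one
  res <- harmonize_do("ATGCTTCTTCTT", rmap, ec)
  expect_error(harmonize_do("ATGCTT", rmap, ec), "region map covers")
  expect_equal(res$ledger$native_rcu[2], 33)
  expect_equal(res$ledger$native_rcu[3],
               unname(burk_tab()$rcu["CTT"]))
})

test_that("GC biasing improves monotonically within the rcu slack", {
  ec <- ecoli_tab()
  mm <- mouse_tab()
  set.seed(13)
  gene <- random_gene(60)
  res <- harmonize_do(gene, mm, ec)
  # slack 0 disables the pass entirely
  expect_identical(apply_gc_bias(res, ec, 56, slack_points = 0)$sequence,
                   res$sequence)
  # |GC - target| never increases
  for (target in c(30, 56, 70)) {
    out <- apply_gc_bias(res, ec, target, slack_points = 10)
    expect_lte(abs(gc_content(out$sequence) - target),
               abs(gc_content(res$sequence) - target))
    expect_identical(translate_cds(out$sequence), translate_cds(gene))
  }
  # an equal-rcu GC-rich/GC-poor pair swings to the GC-rich member
  host <- toy_table(c(AAA = 10, AAG = 10), "gcpair")
  res2 <- harmonize_fo("ATGAAAAAAAAA", host)
  out2 <- apply_gc_bias(res2, host, 99, slack_points = 5)
  expect_identical(out2$ledger$chosen_codon[2:4], rep("AAG", 3))
  expect_match(out2$ledger$rule_note[2], "gc-bias")
})

test_that("forbidden motifs are reported at every overlapping offset", {
  expect_equal(scan_forbidden_motifs("AAGGATCCTT", "GGATCC")$offset, 3L)
  expect_equal(nrow(scan_forbidden_motifs("AAAACCCC", "GGATCC")), 0L)
  # self-similar motif counted at every start
  expect_equal(scan_forbidden_motifs("ATATAT", "ATAT")$offset, c(1L, 3L))
  both <- scan_forbidden_motifs("CCATGGGATCC")
  expect_setequal(both$motif, c("CCATGG", "GGATCC"))
})

test_that("zero-frequency host codons are never chosen when avoidable", {
  host <- toy_table(c(TGT = 5, TGC = 0), "zerohost")
  native <- toy_table(NULL, "uniform")
  res <- harmonize_do("ATGTGC", native, host)
  expect_identical(res$ledger$chosen_codon[2], "TGT")
  res2 <- harmonize_nt("ATGTGC", native, host)
  expect_identical(res2$ledger$chosen_codon[2], "TGT")
})
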