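test_that("pedigrees validate, reorder, and round-trip through files", {
  # founders only
  ped <- as_pedigree(data.frame(animal = c("a", "b", "c"),
                                sire = "0", dam = "0"))
  expect_equal(nrow(ped), 3)
  expect_true(all(is.na(ped$sire)))
  expect_equal(inbreeding_coefficients(ped)$f, rep(0, 3))

  # offspring listed before its sire is reordered, original order kept
  shuffled <- data.frame(animal = c("kid", "pa", "ma"),
                         sire = c("pa", "0", "0"),
                         dam = c("ma", "0", "0"))
  ped2 <- as_pedigree(shuffled)
  expect_equal(ped2$animal, c("pa", "ma", "kid"))
  expect_equal(ped2$file_order[ped2$animal == "kid"], 1L)

  # file round trip with unknown parents coded 0
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(ped2, tmp)
  ped3 <- read_pedigree(tmp)
  expect_equal(ped3$animal, ped2$animal)
  expect_equal(ped3$sire, ped2$sire)

  # error cases
  expect_error(as_pedigree(data.frame(animal = c("x", "x"), sire = "0", dam = "0")),
               "duplicate")
  expect_error(as_pedigree(data.frame(animal = "x", sire = "0", dam = "x")),
               "cycle")
  expect_error(as_pedigree(data.frame(animal = "x", sire = "ghost", dam = "0")),
               "never defined")
  ped4 <- as_pedigree(data.frame(animal = "x", sire = "ghost", dam = "0"),
                      auto_add_founders = TRUE)
  expect_setequal(ped4$animal, c("ghost", "x"))
  # two-member cycle
  expect_error(as_pedigree(data.frame(animal = c("u", "v"),
                                      sire = c("v", "u"), dam = "0")),
               "cycle")
})

test_that("inbreeding from classical matings matches theory", {
  # offspring of full sibs from unrelated founders: F = 0.25
  fs <- as_pedigree(data.frame(
    animal = c("gp", "gm", "s1", "s2", "kid"),
    sire = c("0", "0", "gp", "gp", "s1"),
    dam = c("0", "0", "gm", "gm", "s2")))
  f <- inbreeding_coefficients(fs)$f
  expect_equal(f[fs$animal == "kid"], 0.25)
  # parent-offspring mating with founder parent: F = 0.25
  po <- as_pedigree(data.frame(
    animal = c("pa", "ma", "dau", "kid"),
    sire = c("0", "0", "pa", "pa"),
    dam = c("0", "0", "ma", "dau")))
  expect_equal(inbreeding_coefficients(po)$f[po$animal == "kid"], 0.25)
  # both computation methods agree everywhere
  ped <- as_pedigree(random_pedigree(8, 20, 3, seed = 11))
  expect_equal(inbreeding_coefficients(ped, "tabular")$f,
               inbreeding_coefficients(ped, "meuwissen-luo")$f,
               tolerance = 1e-12)
})

test_that("tabular A matches structure and the path-counting oracle", {
  founders <- as_pedigree(data.frame(animal = letters[1:4], sire = "0", dam = "0"))
  expect_equal(additive_relationship(founders), diag(4),
               ignore_attr = TRUE)
  fs <- as_pedigree(data.frame(
    animal = c("p", "m", "k1", "k2"),
    sire = c("0", "0", "p", "p"),
    dam = c("0", "0", "m", "m")))
  A <- additive_relationship(fs)
  expect_equal(A["k1", "k2"], 0.5)
  expect_equal(diag(A), rep(1, 4), ignore_attr = TRUE)

  # random 100-animal, 3-generation pedigree against the independent oracle
  ped <- as_pedigree(random_pedigree(10, 30, 3, seed = 42))
  A <- additive_relationship(ped)
  A_oracle <- oracle_A_path(ped)
  expect_lt(max(abs(A - A_oracle[rownames(A), colnames(A)])), 1e-12)
  expect_true(isSymmetric(A))
  expect_equal(diag(A), 1 + inbreeding_coefficients(ped)$f,
               ignore_attr = TRUE, tolerance = 1e-14)
  expect_true(all(A[upper.tri(A)] >= 0 & A[upper.tri(A)] < 2))
  # positive definiteness
  expect_no_error(chol(A))
  # memory guard
  expect_error(additive_relationship(ped, max_animals = 10), "refusing")
})

test_that("Henderson A-inverse matches the trio rules and the dense inverse", {
  trio <- as_pedigree(data.frame(animal = c("s", "d", "k"),
                                 sire = c("0", "0", "s"),
                                 dam = c("0", "0", "d")))
  Ainv <- as.matrix(a_inverse(trio))
  expect_equal(Ainv["k", "k"], 2)
  expect_equal(Ainv["k", "s"], -1)
  expect_equal(Ainv["k", "d"], -1)
  expect_equal(Ainv["s", "s"], 1.5)
  expect_equal(Ainv["s", "d"], 0.5)
  # founders only -> identity
  founders <- as_pedigree(data.frame(animal = c("x", "y"), sire = "0", dam = "0"))
  expect_equal(as.matrix(a_inverse(founders)), diag(2), ignore_attr = TRUE)

  # ~200-animal inbred pedigree: Ainv A = I within 1e-8, both methods
  ped <- as_pedigree(random_pedigree(12, 63, 3, seed = 7))
  expect_equal(nrow(ped), 201)
  A <- additive_relationship(ped)
  for (m in c("henderson", "meuwissen-luo")) {
    dev <- max(abs(as.matrix(a_inverse(ped, m) %*% A) - diag(nrow(A))))
    expect_lt(dev, 1e-8)
  }
})

test_that("pruning keeps ancestors, is idempotent and monotone", {
  d <- simulate_design(design_config(), seed = 2)
  retained <- d$covariates$animal[d$covariates$retained]
  pruned <- prune_to_phenotyped(d$pedigree, retained)
  expect_equal(nrow(pruned), 563) # 28 F0 + 81 F1 parents + 454 F2
  expect_true(all(retained %in% pruned$animal))
  # idempotent
  again <- prune_to_phenotyped(pruned, retained)
  expect_equal(again$animal, pruned$animal)
  # monotone: larger id set gives a superset
  sub <- prune_to_phenotyped(d$pedigree, retained[1:100])
  expect_true(all(sub$animal %in% pruned$animal))
  # founder set prunes to itself; empty set to empty pedigree
  f0 <- d$pedigree$animal[d$pedigree$generation == "F0"]
  expect_setequal(prune_to_phenotyped(d$pedigree, f0[1:5])$animal, f0[1:5])
  expect_equal(nrow(prune_to_phenotyped(d$pedigree, character(0))), 0)
  expect_error(prune_to_phenotyped(d$pedigree, "nobody"), "not in pedigree")
})
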