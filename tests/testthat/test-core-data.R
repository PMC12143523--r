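# Data model, file I/O, encodings, missingness filtering, imputation and
# clinal-SNP selection.

test_that("sample table reader validates ids and coordinate ranges", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "samples.tsv")
  df <- data.frame(sample_id = c("A1", "A2", "A3"),
                   group_id = "g1", lat = c(48, 49, 50), lon = c(8, 9, 10))
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  st <- readSampleTable(f)
  expect_equal(nrow(st), 3L)
  expect_type(st$sample_id, "character")

  df$lat[2] <- 95
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSampleTable(f), "A2")

  df$lat[2] <- 49
  df$sample_id[2] <- "A1"
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSampleTable(f), "duplicated")
})

test_that("coded-table reader round-trips and rejects off-domain values", {
  dir <- withr::local_tempdir()
  g <- toy_geno(5, 7, missing = 3)
  f <- file.path(dir, "geno.tsv")
  writeGenotypes(g, f, metaPath = file.path(dir, "markers.tsv"))
  g2 <- readGenotypes(f, format = "coded_table")
  expect_equal(genotypes(g2), genotypes(g))

  txt <- readLines(f)
  txt[2] <- sub("\t0\\.5", "\t0.7", txt[2])
  if (identical(txt[2], readLines(f)[2])) txt[2] <- sub("\t1", "\t0.7", txt[2])
  writeLines(txt, f)
  expect_error(readGenotypes(f, format = "coded_table"), "0.7")
})

test_that("VCF genotypes map GT codes and flag haploid records as plastid", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "chr1\t10\tsnpA\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t20\tsnpB\tC\tT\t.\tPASS\t.\tGT\t./.\t0|1\t0/0",
    "chr1\t30\tsnpC\tG\tA,C\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2",
    "chrC\t40\tplastA\tT\tC\t.\tPASS\t.\tGT\t0\t1\t0"), f)
  expect_warning(g <- readGenotypes(f, format = "vcf"), "multi-allelic")
  v <- genotypes(g)
  expect_equal(dim(v), c(3L, 3L))            # snpC skipped
  expect_equal(unname(v[, "snpA"]), c(1, 0.5, 0))
  expect_equal(unname(v[, "snpB"]), c(NA_real_, 0.5, 1))
  expect_equal(unname(v[, "plastA"]), c(1, 0, 1))
  expect_equal(unname(markerPloidy(g)),
               c("nuclear", "nuclear", "plastid"))
})

test_that("missingness filter drops markers first, then samples, and is idempotent", {
  # 40x10 with one all-missing column; after dropping it, one sample misses
  # 2 of the 9 remaining markers (2/9 > 5%) and is dropped too, while those
  # two markers survive (1/40 < 5%)
  v <- matrix(rep(c(0, 0.5, 1), length.out = 400), 40, 10,
              dimnames = list(sprintf("s%02d", 1:40), sprintf("m%02d", 1:10)))
  v[, 4] <- NA
  v[7, c(1, 9)] <- NA
  g <- GenoMatrix(v)
  f <- filterMissingness(g, 0.05)
  expect_equal(attr(f, "dropped_markers"), "m04")
  expect_equal(attr(f, "dropped_samples"), "s07")
  expect_equal(dim(genotypes(f)), c(39L, 9L))

  f2 <- filterMissingness(f, 0.05)
  expect_equal(genotypes(f2), genotypes(f))

  clean <- toy_geno(6, 6)
  expect_equal(genotypes(filterMissingness(clean)), genotypes(clean))

  allNA <- GenoMatrix(matrix(NA_real_, 3, 3,
                             dimnames = list(letters[1:3], LETTERS[1:3])))
  expect_error(filterMissingness(allNA), "all markers")
})

test_that("recode is the affine map 2x-1 and round-trips exactly", {
  g <- toy_geno(6, 10, missing = 5)
  u <- recodeGeno(g, "unit")
  s <- recodeGeno(g, "signed")
  expect_equal(genotypes(u), genotypes(g))
  expect_equal(genotypes(s), 2 * genotypes(g) - 1)
  expect_true(all(genotypes(s) %in% c(-1, 0, 1, NA)))
  back <- recodeGeno(s, "unit")
  expect_equal(genotypes(back), genotypes(u))
  expect_equal(is.na(genotypes(s)), is.na(genotypes(g)))
})

test_that("mean imputation fills column means and preserves them", {
  v <- matrix(c(1, NA, 0,
                1, 1, NA,
                0.5, 0.5, 0.5), 3, 3,
              dimnames = list(c("a", "b", "c"), c("m1", "m2", "m3")))
  enc <- recodeGeno(GenoMatrix(v), "unit")
  imp <- imputeMean(enc)
  expect_equal(genotypes(imp)["b", "m1"], 0.5)     # mean of {1, 0}
  expect_equal(genotypes(imp)["c", "m2"], 1.0)     # constant column
  expect_equal(genotypes(imp)[, "m3"], genotypes(enc)[, "m3"])
  expect_equal(missingPolicy(imp), "mean_imputed")
  # column means over originally observed entries unchanged
  for (j in 1:3) {
    obs <- !is.na(v[, j])
    expect_equal(mean(genotypes(imp)[obs, j]), mean(v[obs, j]))
  }
  bad <- recodeGeno(GenoMatrix(matrix(c(1, NA, NA, 0.5), 2, 2,
    dimnames = list(c("a", "b"), c("m1", "m2")))), "unit")
  bad@values[, 1] <- NA
  expect_error(imputeMean(bad), "fully missing")
})

test_that("clinal selection keeps perfect clines, drops constants and noise", {
  set.seed(7)
  n <- 50
  samples <- data.frame(sample_id = sprintf("s%02d", 1:n), group_id = "g",
                        lat = runif(n, 40, 55), lon = runif(n, 0, 25))
  v <- cbind(
    clin = (samples$lat - 40) / 15,             # rescaled latitude
    const = rep(0.5, n),
    noise = sample(c(0, 0.5, 1), n, replace = TRUE))
  rownames(v) <- samples$sample_id
  enc <- new("EncodedGeno", values = v, scheme = "unit",
             missingPolicy = "keep_na", columnMeans = numeric(0),
             ploidy = rep("nuclear", 3))
  sel <- selectClinalSnps(enc, samples)
  expect_true(1L %in% sel$keep)
  expect_false(2L %in% sel$keep)
  expect_true(is.na(sel$report$p_lat[2]))
  expect_identical(sel$threshold, 0.05 / 6)
})

test_that("Bonferroni selection controls the family-wise false-selection rate", {
  # 60 replicates x 2000 pure-noise SNPs; P(any selection) <= alpha, so the
  # observed proportion should sit below alpha plus Monte-Carlo slack
  set.seed(123)
  n <- 50
  reps <- 60
  hits <- 0L
  samples <- data.frame(sample_id = sprintf("s%02d", 1:n), group_id = "g",
                        lat = runif(n, 40, 55), lon = runif(n, 0, 25))
  for (r in seq_len(reps)) {
    v <- matrix(rbinom(n * 2000, 2, 0.5) / 2, n, 2000,
                dimnames = list(samples$sample_id, sprintf("x%d", 1:2000)))
    sel <- selectClinalSnps(recodeGeno(GenoMatrix(v), "unit"), samples)
    hits <- hits + (length(sel$keep) > 0L)
  }
  # one-sided 99% binomial envelope for a rate-0.05 process
  expect_lte(hits, qbinom(0.99, reps, 0.05))
})
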