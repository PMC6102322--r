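# PLINK genotype input/output and the canonical in-memory dataset.
#
# A genotype_dataset holds an integer matrix of allele-B dosages
# (samples x markers, NA = missing call), a marker map and a sample table
# with one breed label per sample. All downstream modules consume this
# object; markers are always kept sorted by (chromosome, position).

VALID_ALLELES <- c("A", "C", "G", "T", "1", "2", "0")

#' Construct a multi-breed genotype dataset
#'
#' The canonical container for diploid SNP-array genotypes. Genotype calls
#' are stored as counts of `allele_b` (0, 1, 2) with `NA` for missing calls.
#' Markers are sorted by (chromosome, position) on construction; chromosome
#' labels are opaque strings ordered numerically where possible.
#'
#' @param calls Integer matrix, samples x markers, entries in
#'   `c(0, 1, 2, NA)`.
#' @param map Data frame with columns `marker_id`, `chromosome`,
#'   `position_bp` (1-based base pairs), `allele_a`, `allele_b`.
#' @param samples Data frame with columns `sample_id` and `breed`.
#' @return An object of class `genotype_dataset`: a list with elements
#'   `calls`, `map`, `samples`.
#' @examples
#' map <- data.frame(marker_id = c("m1", "m2"), chromosome = "1",
#'                   position_bp = c(100L, 200L),
#'                   allele_a = "A", allele_b = "C")
#' smp <- data.frame(sample_id = c("s1", "s2"), breed = "B1")
#' gd <- genotype_dataset(rbind(c(0, 1), c(2, NA)), map, smp)
#' @export
genotype_dataset <- function(calls, map, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  map <- as.data.frame(map)
  samples <- as.data.frame(samples)
  map$chromosome <- as.character(map$chromosome)
  map$marker_id <- as.character(map$marker_id)
  map$position_bp <- as.integer(map$position_bp)
  samples$sample_id <- as.character(samples$sample_id)
  samples$breed <- as.character(samples$breed)

  if (nrow(calls) != nrow(samples))
    stopf("calls has %d rows but %d samples given", nrow(calls), nrow(samples))
  if (ncol(calls) != nrow(map))
    stopf("calls has %d columns but %d markers given", ncol(calls), nrow(map))
  if (anyDuplicated(map$marker_id))
    stopf("duplicate marker_id: %s",
          paste(unique(map$marker_id[duplicated(map$marker_id)]), collapse = ", "))
  if (any(!is.na(calls) & !(calls %in% 0:2)))
    stopf("genotype calls must be 0, 1, 2 or NA")
  if (any(map$position_bp < 0))
    stopf("negative marker position")
  if (any(!nzchar(samples$breed)) || anyNA(samples$breed))
    stopf("every sample needs a non-empty breed label")

  ord <- marker_order(map)
  map <- map[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  rownames(map) <- NULL
  # co-located markers keep their input order
  dup <- stats::ave(map$position_bp, map$chromosome,
                    FUN = function(p) duplicated(p))
  if (any(dup == 1))
    warnf("%d marker(s) share a position with a preceding marker; input order kept",
          sum(dup == 1))
  dimnames(calls) <- list(samples$sample_id, map$marker_id)

  structure(list(calls = calls, map = map, samples = samples),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples x %d markers, %d breed(s), %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls),
              length(unique(x$samples$breed)),
              length(unique(x$map$chromosome))))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing call rate: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$calls)

# ---- PED/MAP ----------------------------------------------------------------

empty_map <- function() {
  data.frame(marker_id = character(), chromosome = character(),
             position_bp = integer(), allele_a = character(),
             allele_b = character(), stringsAsFactors = FALSE)
}

read_map_file <- function(path) {
  if (file.size(path) == 0L) return(empty_map()[, 1:3])
  mp <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (!ncol(mp) %in% c(3L, 4L))
    stopf("%s: expected 3 or 4 columns, got %d", path, ncol(mp))
  pos_col <- ncol(mp)  # last column is bp whether or not cM column present
  data.frame(marker_id = mp[[2]], chromosome = mp[[1]],
             position_bp = as.integer(mp[[pos_col]]),
             stringsAsFactors = FALSE)
}

read_ped_pair <- function(prefix) {
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  for (p in c(ped_path, map_path))
    if (!file.exists(p)) stopf("companion file missing: %s", p)
  map <- read_map_file(map_path)
  m <- nrow(map)

  fields <- scan(ped_path, what = character(), quiet = TRUE)
  n_col <- 6L + 2L * m
  if (length(fields) %% n_col != 0L)
    stopf("%s: field count %d not a multiple of %d (6 + 2 x %d markers)",
          ped_path, length(fields), n_col, m)
  n <- length(fields) %/% n_col
  ped <- matrix(fields, nrow = n, byrow = TRUE)

  samples <- data.frame(sample_id = ped[, 2], breed = ped[, 1],
                        stringsAsFactors = FALSE)
  a1 <- ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- ped[, 6L + 2L * seq_len(m), drop = FALSE]
  bad <- setdiff(unique(c(a1, a2)), VALID_ALLELES)
  if (length(bad))
    stopf("invalid allele code(s): %s", paste(bad, collapse = ", "))
  if (any((a1 == "0") != (a2 == "0")))
    stopf("half-missing genotype call (one allele '0')")

  calls <- matrix(NA_integer_, n, m)
  allele_a <- allele_b <- character(m)
  for (k in seq_len(m)) {
    obs <- sort(setdiff(unique(c(a1[, k], a2[, k])), "0"))
    if (length(obs) > 2L)
      stopf("marker %s has >2 alleles", map$marker_id[k])
    # PED carries no allele order: canonicalise as sorted (allele_a < allele_b)
    allele_a[k] <- if (length(obs) >= 1L) obs[1] else "0"
    allele_b[k] <- if (length(obs) == 2L) obs[2] else "0"
    g <- (a1[, k] == allele_b[k]) + (a2[, k] == allele_b[k])
    g[a1[, k] == "0"] <- NA_integer_
    calls[, k] <- g
  }
  map$allele_a <- allele_a
  map$allele_b <- allele_b
  genotype_dataset(calls, map, samples)
}

# ---- BED/BIM/FAM ------------------------------------------------------------

# 2-bit PLINK bed codes (SNP-major): 00 hom A1, 01 missing, 10 het, 11 hom A2.
# With allele_a = A1 and allele_b = A2, dosage of allele_b is 0 / NA / 1 / 2.
bed_decode_table <- function() {
  code_to_dosage <- c(0L, NA_integer_, 1L, 2L)  # indices 1..4 for codes 0..3
  tab <- matrix(NA_integer_, 256L, 4L)
  for (byte in 0:255)
    tab[byte + 1L, ] <- code_to_dosage[1L + c(
      bitwAnd(byte, 3L), bitwAnd(bitwShiftR(byte, 2L), 3L),
      bitwAnd(bitwShiftR(byte, 4L), 3L), bitwAnd(bitwShiftR(byte, 6L), 3L))]
  tab
}

read_bed_trio <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  bim_path <- paste0(prefix, ".bim")
  fam_path <- paste0(prefix, ".fam")
  for (p in c(bed_path, bim_path, fam_path))
    if (!file.exists(p)) stopf("companion file missing: %s", p)

  bim <- utils::read.table(bim_path, header = FALSE, colClasses = "character")
  if (ncol(bim) != 6L) stopf("%s: expected 6 columns", bim_path)
  map <- data.frame(marker_id = bim[[2]], chromosome = bim[[1]],
                    position_bp = as.integer(bim[[4]]),
                    allele_a = bim[[5]], allele_b = bim[[6]],
                    stringsAsFactors = FALSE)
  bad <- setdiff(unique(c(map$allele_a, map$allele_b)), VALID_ALLELES)
  if (length(bad))
    stopf("invalid allele code(s) in %s: %s", bim_path, paste(bad, collapse = ", "))

  fam <- utils::read.table(fam_path, header = FALSE, colClasses = "character")
  samples <- data.frame(sample_id = fam[[2]], breed = fam[[1]],
                        stringsAsFactors = FALSE)
  n <- nrow(samples); m <- nrow(map)

  raw <- readBin(bed_path, "raw", n = file.info(bed_path)$size)
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stopf("%s: not a PLINK bed file (bad magic bytes)", bed_path)
  if (raw[3] != as.raw(0x01))
    stopf("%s: only SNP-major bed files are supported", bed_path)
  bpm <- ceiling(n / 4)  # bytes per marker
  if (length(raw) - 3L != bpm * m)
    stopf("%s: size %d inconsistent with %d samples x %d markers",
          bed_path, length(raw), n, m)

  tab <- bed_decode_table()
  bytes <- matrix(as.integer(raw[-(1:3)]), nrow = bpm)  # bpm x m
  calls <- matrix(NA_integer_, n, m)
  for (slot in 1:4) {  # position of the sample within its byte
    rows <- seq.int(slot, length.out = max(0L, (n - slot) %/% 4L + 1L), by = 4L)
    if (!length(rows)) next
    calls[rows, ] <- tab[bytes[seq_along(rows), , drop = FALSE] + 1L, slot]
  }
  genotype_dataset(calls, map, samples)
}

#' Read PLINK genotypes (PED/MAP or BED/BIM/FAM)
#'
#' Reads either the text (`.ped` + `.map`) or binary SNP-major
#' (`.bed` + `.bim` + `.fam`) PLINK dialect, whichever exists at
#' `prefix`. Markers are re-sorted by (chromosome, position) and breed
#' labels are taken from the family-ID column unless `breed_table`
#' overrides them.
#'
#' In PED mode the allele order is canonicalised (sorted allele codes,
#' `allele_a < allele_b`) because the text format does not record it; the
#' binary dialect preserves A1/A2 as `allele_a`/`allele_b`. Genotypes are
#' dosages of `allele_b`; `0 0` (text) and the `01` code (binary) become
#' `NA`.
#'
#' @param prefix Path prefix (no extension) of the fileset.
#' @param breed_table Optional sample-to-breed override: a data frame with
#'   columns `sample_id`, `breed`, or a named character vector
#'   (names = sample ids). Missing entries fall back to the family ID.
#' @return A [genotype_dataset()].
#' @export
read_plink <- function(prefix, breed_table = NULL) {
  gd <- if (file.exists(paste0(prefix, ".bed"))) {
    read_bed_trio(prefix)
  } else if (file.exists(paste0(prefix, ".ped"))) {
    read_ped_pair(prefix)
  } else {
    stopf("no .bed or .ped file found at prefix '%s'", prefix)
  }
  if (!is.null(breed_table)) {
    if (is.data.frame(breed_table)) {
      lut <- stats::setNames(as.character(breed_table$breed),
                             as.character(breed_table$sample_id))
    } else {
      lut <- breed_table
    }
    hit <- gd$samples$sample_id %in% names(lut)
    gd$samples$breed[hit] <- unname(lut[gd$samples$sample_id[hit]])
  }
  gd
}

#' Write PLINK genotypes
#'
#' Emits either `prefix.ped`/`prefix.map` (text) or
#' `prefix.bed`/`prefix.bim`/`prefix.fam` (binary, SNP-major). Breed labels
#' are stored as the family ID; missing calls are written as `0 0` (text)
#' or the PLINK missing code (binary). Output is readable by
#' [read_plink()] and by standard PLINK.
#'
#' @param dataset A [genotype_dataset()].
#' @param prefix Output path prefix (no extension).
#' @param dialect `"ped"` for text, `"bed"` for binary.
#' @return Invisibly, the vector of files written.
#' @export
write_plink <- function(dataset, prefix, dialect = c("ped", "bed")) {
  dialect <- match.arg(dialect)
  map <- dataset$map
  samples <- dataset$samples
  calls <- dataset$calls
  n <- nrow(calls); m <- ncol(calls)

  if (dialect == "ped") {
    map_path <- paste0(prefix, ".map")
    ped_path <- paste0(prefix, ".ped")
    if (m > 0) {
      utils::write.table(
        data.frame(map$chromosome, map$marker_id, 0, map$position_bp),
        map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    } else {
      writeLines(character(0), map_path)
    }

    geno <- matrix("0 0", n, m)
    if (m > 0) {
      aa <- matrix(paste(map$allele_a, map$allele_a), n, m, byrow = TRUE)
      ab <- matrix(paste(map$allele_a, map$allele_b), n, m, byrow = TRUE)
      bb <- matrix(paste(map$allele_b, map$allele_b), n, m, byrow = TRUE)
      geno[which(calls == 0L)] <- aa[which(calls == 0L)]
      geno[which(calls == 1L)] <- ab[which(calls == 1L)]
      geno[which(calls == 2L)] <- bb[which(calls == 2L)]
    }
    lines <- paste(samples$breed, samples$sample_id, 0, 0, 0, -9,
                   if (m > 0) apply(geno, 1, paste, collapse = " ") else "")
    lines <- sub(" $", "", lines)
    writeLines(lines, ped_path)
    return(invisible(c(ped_path, map_path)))
  }

  bim_path <- paste0(prefix, ".bim")
  fam_path <- paste0(prefix, ".fam")
  bed_path <- paste0(prefix, ".bed")
  if (m > 0) {
    utils::write.table(
      data.frame(map$chromosome, map$marker_id, 0, map$position_bp,
                 map$allele_a, map$allele_b),
      bim_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    writeLines(character(0), bim_path)
  }
  utils::write.table(
    data.frame(samples$breed, samples$sample_id, 0, 0, 0, -9),
    fam_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  # dosage -> 2-bit code: 0 -> 00, 1 -> 10, 2 -> 11, NA -> 01
  if (m > 0) {
    g <- calls
    cd <- matrix(0L, n, m)
    cd[which(g == 1L)] <- 2L
    cd[which(g == 2L)] <- 3L
    cd[which(is.na(g))] <- 1L
    full <- matrix(0L, 4L * ceiling(n / 4), m)
    full[seq_len(n), ] <- cd
    packed <- full[seq(1, nrow(full), 4), , drop = FALSE] +
      4L * full[seq(2, nrow(full), 4), , drop = FALSE] +
      16L * full[seq(3, nrow(full), 4), , drop = FALSE] +
      64L * full[seq(4, nrow(full), 4), , drop = FALSE]
    body <- as.raw(as.vector(packed))
  } else {
    body <- raw(0)
  }
  con <- file(bed_path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(body, con)
  invisible(c(bed_path, bim_path, fam_path))
}
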