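# VCF / genetic-map input-output and dataset QC.
#
# Variant tables are plain data.frames (chrom, pos, id, ref, alt, cm) with
# strictly increasing positions per chromosome and exactly biallelic records.
# Genotype matrices hold codes 0 (hom-ref), 1 (het), 2 (hom-alt), NA
# (missing) with individuals in rows and sites in columns, plus the sparse
# phase-set annotations parsed from phased GT + PS.

#' Construct and validate a variant table
#'
#' @param chrom,pos,id,ref,alt vectors describing biallelic variant records.
#' @param cm genetic positions in centimorgans (may be `NA` until a map is
#'   interpolated with [interpolate_cm()]).
#' @return A `data.frame` with class `variant_table`.
#' @export
variant_table <- function(chrom, pos, id = NULL, ref = "A", alt = "C",
                          cm = NA_real_) {
  vt <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    id = if (is.null(id)) paste0(chrom, "_", pos) else as.character(id),
    ref = as.character(ref), alt = as.character(alt), cm = as.numeric(cm),
    stringsAsFactors = FALSE
  )
  for (ch in unique(vt$chrom)) {
    p <- vt$pos[vt$chrom == ch]
    if (any(diff(p) <= 0)) stop("positions must be strictly increasing within a chromosome")
  }
  if (any(vt$ref == vt$alt)) stop("ref and alt alleles must differ")
  ok <- !is.na(vt$cm)
  if (any(ok) && any(diff(vt$cm[ok]) < 0)) stop("cm must be non-decreasing")
  class(vt) <- c("variant_table", "data.frame")
  vt
}

#' Construct a genotype matrix container
#'
#' @param codes integer matrix, individuals x sites, entries in
#'   \{0, 1, 2, NA\}.
#' @param samples character vector of sample identifiers.
#' @param phase_sets data.frame with columns `ind` (row index), `var` (site
#'   index), `ps` (phase-set id) and `allele1` (allele carried by the first
#'   haplotype), one row per phased het belonging to a read-derived phase set.
#' @return A list with class `genotype_matrix`.
#' @export
genotype_matrix <- function(codes, samples = NULL,
                            phase_sets = empty_phase_sets()) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (any(!codes[!is.na(codes)] %in% 0:2)) stop("genotype codes must be 0/1/2/NA")
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(codes)))
  if (length(samples) != nrow(codes)) stop("samples length must match rows of codes")
  if (nrow(phase_sets)) {
    het <- codes[cbind(phase_sets$ind, phase_sets$var)] == 1L
    if (any(is.na(het)) || !all(het))
      stop("phase-set entries must sit at het, non-missing genotypes")
  }
  structure(list(codes = codes, samples = as.character(samples),
                 phase_sets = phase_sets),
            class = "genotype_matrix")
}

empty_phase_sets <- function() {
  data.frame(ind = integer(), var = integer(), ps = integer(),
             allele1 = integer())
}

parse_region <- function(region) {
  if (is.null(region)) return(NULL)
  m <- regmatches(region, regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region))[[1]]
  if (!length(m)) stop("malformed region: ", region)
  list(chrom = m[2],
       start = if (nzchar(m[4])) as.integer(m[4]) else NA_integer_,
       end = if (nzchar(m[5])) as.integer(m[5]) else NA_integer_)
}

gt_to_code <- function(gt) {
  # decode a character matrix of GT strings into 0/1/2/NA codes
  u <- unique(as.vector(gt))
  code <- vapply(u, function(g) {
    al <- strsplit(g, "[/|]")[[1]]
    if (!length(al) || any(al == ".") || any(is.na(al))) return(NA_integer_)
    sum(as.integer(al))
  }, integer(1))
  matrix(code[match(gt, u)], nrow = nrow(gt))
}

#' Read biallelic genotypes from a VCF file
#'
#' Parses GT (and, when present, PS) from a plain or gzipped multi-sample
#' VCF. Multiallelic records, symbolic alleles and duplicated positions are
#' skipped with a message. Phased het genotypes carrying a PS value become
#' phase-set annotations.
#'
#' @param vcf_path path to a VCF (optionally gzipped).
#' @param region optional `"chrom"` or `"chrom:start-end"` filter; the bp
#'   interval is half-open `[start, end)`.
#' @return list with elements `vt` ([variant_table()]) and `gm`
#'   ([genotype_matrix()]).
#' @export
read_genotypes <- function(vcf_path, region = NULL) {
  core <- read_vcf_core(vcf_path, region)
  core[c("vt", "gm")]
}

# shared VCF record parsing; also returns the raw GT strings (variants x
# samples) so phased haplotypes can be extracted without re-deriving the
# record filter
read_vcf_core <- function(vcf_path, region = NULL) {
  if (!file.exists(vcf_path)) stop("cannot read VCF: ", vcf_path)
  vcf <- VariantAnnotation::readVcf(vcf_path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(rr$REF)
  nalt <- lengths(rr$ALT)
  alt <- rep(NA_character_, length(rr))
  alt[nalt == 1] <- vapply(as.list(rr$ALT[nalt == 1]), as.character, "")

  keep <- nalt == 1 & !is.na(alt) & nzchar(ref) & nzchar(alt) &
    !grepl("[<>\\[\\]]", alt)
  n_multi <- sum(!keep)
  dup <- duplicated(paste(chrom, pos))
  keep <- keep & !dup
  if (n_multi + sum(dup) > 0)
    message(sprintf("read_genotypes: skipped %d multiallelic/symbolic and %d duplicated-position records",
                    n_multi, sum(dup)))

  reg <- parse_region(region)
  if (!is.null(reg)) {
    keep <- keep & chrom == reg$chrom
    if (!is.na(reg$start)) keep <- keep & pos >= reg$start & pos < reg$end
  }
  if (!any(keep)) stop("no variants in region")

  vt <- variant_table(chrom[keep], pos[keep], names(rr)[keep],
                      ref[keep], alt[keep])
  gt <- VariantAnnotation::geno(vcf)$GT[keep, , drop = FALSE]
  codes <- t(gt_to_code(gt))

  phase_sets <- empty_phase_sets()
  gtypes <- VariantAnnotation::geno(vcf)
  if ("PS" %in% names(gtypes)) {
    ps <- gtypes$PS[keep, , drop = FALSE]
    if (is.list(ps)) ps <- matrix(vapply(ps, function(x) if (length(x)) x[1] else NA_integer_, integer(1)), nrow = nrow(ps))
    phased <- grepl("|", gt, fixed = TRUE)
    het <- t(codes) == 1L
    sel <- which(phased & het & !is.na(ps), arr.ind = TRUE)
    if (nrow(sel)) {
      a1 <- as.integer(substr(gt[sel], 1, 1))
      phase_sets <- data.frame(ind = sel[, 2], var = sel[, 1],
                               ps = as.integer(ps[sel]), allele1 = a1)
      phase_sets <- phase_sets[order(phase_sets$ind, phase_sets$var), ]
      rownames(phase_sets) <- NULL
    }
  }
  gm <- genotype_matrix(codes, colnames(gt), phase_sets)
  list(vt = vt, gm = gm, gt = gt)
}

#' Read a haplotype scaffold from a phased VCF
#'
#' Retains one entry per (individual, variant) that is present in both the
#' scaffold and the main panel, heterozygous in the main panel and phased
#' ("|") in the scaffold. Everything else is ignored; unphased scaffold
#' records are skipped with a warning.
#'
#' @param vcf_path scaffold VCF with phased GT.
#' @param main [variant_table()] of the main panel.
#' @param gm [genotype_matrix()] of the main panel (het lookup).
#' @param samples samples to consider, default all of `gm$samples`.
#' @return data.frame `ind`, `var`, `allele` (first-haplotype allele), class
#'   `scaffold`.
#' @export
read_scaffold <- function(vcf_path, main, gm, samples = gm$samples) {
  if (!file.exists(vcf_path)) stop("cannot read VCF: ", vcf_path)
  vcf <- VariantAnnotation::readVcf(vcf_path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  nalt <- lengths(rr$ALT)
  alt <- rep(NA_character_, length(rr))
  alt[nalt == 1] <- vapply(as.list(rr$ALT[nalt == 1]), as.character, "")
  key <- paste(as.character(GenomicRanges::seqnames(rr)),
               BiocGenerics::start(rr), as.character(rr$REF), alt)
  main_key <- paste(main$chrom, main$pos, main$ref, main$alt)
  var_idx <- match(key, main_key)   # scaffold record -> main variant

  gt <- VariantAnnotation::geno(vcf)$GT
  smp <- match(colnames(gt), gm$samples)
  use_s <- which(!is.na(smp) & gm$samples[smp] %in% samples)

  out <- list()
  n_unphased <- 0L
  for (s in use_s) {
    i <- smp[s]
    rec <- which(!is.na(var_idx))
    for (r in rec) {
      v <- var_idx[r]
      g <- gt[r, s]
      code <- gm$codes[i, v]
      if (is.na(code) || code != 1L) next
      if (!grepl("|", g, fixed = TRUE)) {
        if (g != "./." && !grepl("^\\.", g)) n_unphased <- n_unphased + 1L
        next
      }
      al <- strsplit(g, "|", fixed = TRUE)[[1]]
      if (length(al) != 2 || any(al == ".")) next
      out[[length(out) + 1L]] <- c(i, v, as.integer(al[1]))
    }
  }
  if (n_unphased > 0)
    warning(sprintf("read_scaffold: skipped %d unphased scaffold records", n_unphased))
  sc <- if (length(out)) {
    m <- do.call(rbind, out)
    data.frame(ind = m[, 1], var = m[, 2], allele = m[, 3])
  } else data.frame(ind = integer(), var = integer(), allele = integer())
  sc <- sc[!duplicated(sc[c("ind", "var")]), ]
  rownames(sc) <- NULL
  class(sc) <- c("scaffold", "data.frame")
  sc
}

#' Read a genetic map
#'
#' Accepts HapMap-style 3-column text: either `pos rate cM` or
#' `chrom pos cM`; a header line is detected and skipped.
#'
#' @param path whitespace-delimited map file.
#' @return data.frame `pos`, `cm` with class `genetic_map`.
#' @export
read_genetic_map <- function(path) {
  raw <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 3) stop("genetic map must have 3 columns")
  # a header row has non-numeric entries in the numeric columns (2 and 3)
  if (nrow(raw) > 1 &&
      (is.na(suppressWarnings(as.numeric(raw[1, 2]))) ||
       is.na(suppressWarnings(as.numeric(raw[1, 3])))))
    raw <- raw[-1, , drop = FALSE]
  col1 <- suppressWarnings(as.numeric(raw[, 1]))
  chrom_style <- any(is.na(col1)) ||
    (nrow(raw) > 1 && length(unique(raw[, 1])) == 1)
  if (chrom_style) {
    pos <- as.numeric(raw[, 2]); cm <- as.numeric(raw[, 3])
  } else {
    pos <- col1; cm <- as.numeric(raw[, 3])
  }
  if (any(is.na(pos)) || any(is.na(cm))) stop("malformed genetic map")
  if (any(diff(pos) <= 0)) stop("map positions must be strictly increasing")
  if (any(diff(cm) < 0)) stop("map cM must be non-decreasing")
  structure(data.frame(pos = pos, cm = cm),
            class = c("genetic_map", "data.frame"))
}

#' Interpolate genetic positions
#'
#' Piecewise-linear interpolation between map anchors; positions beyond the
#' map ends are extrapolated at a constant 1 cM/Mb.
#'
#' @param map a [read_genetic_map()] result.
#' @param positions sorted bp positions to interpolate.
#' @return numeric vector of cM, monotone non-decreasing in position.
#' @export
interpolate_cm <- function(map, positions) {
  rate <- 1e-6  # 1 cM/Mb in cM/bp, used beyond the anchored range
  if (nrow(map) == 1) return(map$cm[1] + (positions - map$pos[1]) * rate)
  cm <- approx(map$pos, map$cm, xout = positions, rule = 1)$y
  lo <- positions < map$pos[1]
  hi <- positions > map$pos[nrow(map)]
  cm[lo] <- map$cm[1] - (map$pos[1] - positions[lo]) * rate
  cm[hi] <- map$cm[nrow(map)] + (positions[hi] - map$pos[nrow(map)]) * rate
  cm
}

#' Apply dataset QC filters
#'
#' Removes variants with more than `max_var_missing` missing genotypes, then
#' individuals with more than `max_ind_missing` missingness over the
#' surviving variants -- variants first, then individuals. Thresholds are
#' strict (`>`), so exactly-5\%-missing records are retained.
#'
#' @param gm [genotype_matrix()].
#' @param vt [variant_table()].
#' @param max_var_missing,max_ind_missing missingness fractions (default
#'   0.05 each).
#' @return list `gm`, `vt` with phase-set annotations re-indexed, plus
#'   `removed_variants` and `removed_individuals` counts.
#' @export
apply_qc_filters <- function(gm, vt, max_var_missing = 0.05,
                             max_ind_missing = 0.05) {
  miss_v <- colMeans(is.na(gm$codes))
  keep_v <- miss_v <= max_var_missing
  if (!any(keep_v)) stop("QC removed all variants")
  codes <- gm$codes[, keep_v, drop = FALSE]
  miss_i <- rowMeans(is.na(codes))
  keep_i <- miss_i <= max_ind_missing
  if (!any(keep_i)) stop("QC removed all individuals")
  codes <- codes[keep_i, , drop = FALSE]

  vmap <- cumsum(keep_v); vmap[!keep_v] <- NA
  imap <- cumsum(keep_i); imap[!keep_i] <- NA
  ps <- gm$phase_sets
  if (nrow(ps)) {
    ps$var <- vmap[ps$var]
    ps$ind <- imap[ps$ind]
    ps <- ps[!is.na(ps$var) & !is.na(ps$ind), , drop = FALSE]
    rownames(ps) <- NULL
  }
  message(sprintf("QC: removed %d/%d variants, %d/%d individuals",
                  sum(!keep_v), length(keep_v), sum(!keep_i), length(keep_i)))
  out_vt <- vt[keep_v, , drop = FALSE]
  rownames(out_vt) <- NULL
  class(out_vt) <- class(vt)
  list(gm = genotype_matrix(codes, gm$samples[keep_i], ps), vt = out_vt,
       removed_variants = sum(!keep_v), removed_individuals = sum(!keep_i))
}

#' Intersect a main panel with a reference panel
#'
#' Aligns sites matching on (chrom, pos, ref, alt); records with ref/alt
#' exchanged are matched with a flip flag so reference allele codes can be
#' inverted. All other records are dropped.
#'
#' @param main,ref [variant_table()]s sorted by position.
#' @return data.frame `main_idx`, `ref_idx`, `flip`.
#' @export
intersect_with_reference <- function(main, ref) {
  main_key <- paste(main$chrom, main$pos, main$ref, main$alt)
  ref_key <- paste(ref$chrom, ref$pos, ref$ref, ref$alt)
  ref_swap <- paste(ref$chrom, ref$pos, ref$alt, ref$ref)
  exact <- match(main_key, ref_key)
  swap <- match(main_key, ref_swap)
  use_swap <- is.na(exact) & !is.na(swap)
  idx <- ifelse(is.na(exact), swap, exact)
  keep <- !is.na(idx)
  if (!any(keep)) stop("no overlap between main and reference panels")
  dropped <- sum(!keep)
  if (dropped) message(sprintf("intersect: dropped %d main-panel sites absent from reference", dropped))
  data.frame(main_idx = which(keep), ref_idx = idx[keep],
             flip = use_swap[keep])
}

#' Write phased haplotypes to VCF
#'
#' Writes GT phased (`a|b`) and, when `certainty` is supplied, a per-site PP
#' FORMAT field with the phasing certainty of each het. Output round-trips
#' through [read_genotypes()].
#'
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @param vt [variant_table()].
#' @param haplotypes complete 2N x L binary matrix, rows `2i-1`, `2i` being
#'   individual `i`'s haplotypes.
#' @param samples sample names (default `S1..SN`).
#' @param certainty optional N x L numeric matrix of phasing certainties.
#' @export
write_phased_vcf <- function(path, vt, haplotypes, samples = NULL,
                             certainty = NULL) {
  if (any(is.na(haplotypes))) stop("haplotypes must be complete (no missing)")
  M <- nrow(haplotypes); L <- ncol(haplotypes)
  if (M %% 2 != 0 || L != nrow(vt)) stop("haplotype matrix shape mismatch")
  N <- M %/% 2
  if (is.null(samples)) samples <- paste0("S", seq_len(N))
  h1 <- haplotypes[seq(1, M, 2), , drop = FALSE]
  h2 <- haplotypes[seq(2, M, 2), , drop = FALSE]
  gt <- matrix(paste0(h1, "|", h2), nrow = N)  # N x L
  fmt <- "GT"
  if (!is.null(certainty)) {
    pp <- ifelse(is.na(certainty), ".", sprintf("%.4f", certainty))
    gt <- matrix(paste0(gt, ":", pp), nrow = N)
    fmt <- "GT:PP"
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=haplophaser",
    paste0("##contig=<ID=", unique(vt$chrom), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (!is.null(certainty))
      '##FORMAT=<ID=PP,Number=1,Type=Float,Description="Phasing certainty">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(vt$chrom, vt$pos, vt$id, vt$ref, vt$alt, ".", ".", ".", fmt,
                sep = "\t")
  body <- paste(body, apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  write_vcf_lines(path, c(hdr, body))
  invisible(path)
}

# .gz output is block-gzipped (bgzf) so htslib-based readers can seek in it
write_vcf_lines <- function(path, lines) {
  if (grepl("\\.gz$", path)) {
    tmp <- tempfile(fileext = ".vcf")
    on.exit(unlink(tmp))
    writeLines(lines, tmp)
    Rsamtools::bgzip(tmp, dest = path, overwrite = TRUE)
  } else {
    writeLines(lines, path)
  }
}

#' Write an unphased genotype VCF (with optional phase sets)
#'
#' Companion writer for simulated fixtures: emits `a/b` genotypes and, for
#' sites belonging to a phase set, phased `a|b` genotypes with a PS value.
#'
#' @param path output path.
#' @param vt [variant_table()].
#' @param gm [genotype_matrix()]; its `phase_sets` are written as PS.
#' @export
write_genotype_vcf <- function(path, vt, gm) {
  codes <- gm$codes
  N <- nrow(codes); L <- ncol(codes)
  gt <- matrix("./.", N, L)
  gt[!is.na(codes) & codes == 0L] <- "0/0"
  gt[!is.na(codes) & codes == 1L] <- "0/1"
  gt[!is.na(codes) & codes == 2L] <- "1/1"
  ps <- matrix(".", N, L)
  pst <- gm$phase_sets
  if (nrow(pst)) {
    sel <- cbind(pst$ind, pst$var)
    gt[sel] <- paste0(pst$allele1, "|", 1L - pst$allele1)
    ps[sel] <- as.character(pst$ps)
  }
  cells <- matrix(paste0(gt, ":", ps), nrow = N)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=haplophaser-sim",
    paste0("##contig=<ID=", unique(vt$chrom), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=PS,Number=1,Type=Integer,Description="Phase set">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  body <- paste(vt$chrom, vt$pos, vt$id, vt$ref, vt$alt, ".", ".", ".",
                "GT:PS", sep = "\t")
  body <- paste(body, apply(cells, 2, paste, collapse = "\t"), sep = "\t")
  write_vcf_lines(path, c(hdr, body))
  invisible(path)
}
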