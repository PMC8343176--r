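# shared builders for small in-code fixtures

# genotype matrix from a character matrix and evenly spaced positions
make_gm <- function(mat, chrom = "chr1", spacing = 1000L, start = 1L) {
  m <- ncol(mat)
  genotype_matrix(mat, data.frame(chrom = chrom,
                                  pos = seq(start, by = spacing,
                                            length.out = m)))
}

# binned marker object straight from a genotype matrix (one marker per col)
make_bins <- function(mat, chrom = "chr1", window_bp = 100000L) {
  m <- ncol(mat)
  starts <- (seq_len(m) - 1L) * window_bp
  bm <- binned_markers(mat, data.frame(chrom = chrom, start = starts,
                                       end = starts + window_bp,
                                       label = sprintf("%s:%07d", chrom,
                                                       starts)))
  rilqtl:::recompute_marker_qc(bm)
}

# quick small simulated population run through the genotyping front end
quick_sim <- function(seed = 1, n_lines = 40, n_chrom = 1,
                      len = 4e6, map_cM = 50, n_snps = 800,
                      depth = 1, err = 0.01) {
  cfg <- sim_config(n_lines = n_lines, n_chromosomes = n_chrom,
                    chrom_length_bp = len, map_length_cM = map_cM,
                    n_snps_per_chrom = n_snps, mean_depth = depth,
                    call_error = err, seed = seed)
  truth <- simulate_ril_genomes(cfg)
  vcs <- simulate_variant_calls(truth)
  list(cfg = cfg, truth = truth, vcs = vcs)
}

# align truth genotypes to a diagnostic SNP subset
truth_at <- function(truth, chrom, pos) {
  key_t <- paste(truth$loci$chrom, truth$loci$pos)
  idx <- match(paste(chrom, pos), key_t)
  truth$genotypes$geno[, idx, drop = FALSE]
}

# a tiny hand-written VCF on disk; returns the path
write_toy_vcf <- function(lines, dir = withr::local_tempdir(
                            .local_envir = parent.frame())) {
  path <- file.path(dir, "toy.vcf")
  writeLines(lines, path)
  path
}

toy_vcf_header <- function(samples = c("S1", "S2")) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}
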