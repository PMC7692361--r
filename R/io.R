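# Readers and writers for the interchange formats: depth TSV
# (samtools-depth dialect), VCF 4.2, FASTA, GFF3, window/region TSVs,
# and the plain-text truth file.

#' Read a samtools-depth style table
#'
#' @param path 3-column TSV: chrom, 1-based position, depth (no header).
#' @return Tibble `chrom`, `pos`, `depth`.
#' @export
read_depth <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "pos", "depth"))
  tibble::as_tibble(dt)
}

#' @rdname read_depth
#' @param x depth tibble.
#' @export
write_depth <- function(x, path) {
  data.table::fwrite(x[, c("chrom", "pos", "depth")], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

VCF_INFO_KEYS <- c("FS", "QD", "MQ", "SOR", "MQRankSum", "ReadPosRankSum")

#' Write variant records as VCF 4.2
#'
#' @param records variant tibble (see [simulate_variants()] /
#'   [hard_filter()]).
#' @param path output path.
#' @param sample_name sample column name; default `"sample"`.
#' @export
write_vcf <- function(records, path, sample_name = "sample") {
  records <- dplyr::arrange(tibble::as_tibble(records), .data$chrom, .data$pos)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ztrscan",
    sprintf('##INFO=<ID=%s,Number=1,Type=Float,Description="%s">',
            VCF_INFO_KEYS, VCF_INFO_KEYS),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_name)
  )
  info <- vapply(seq_len(nrow(records)), function(i) {
    vals <- vapply(VCF_INFO_KEYS, function(k) {
      v <- records[[k]][i]
      if (is.null(v) || is.na(v)) NA_character_ else sprintf("%s=%.4g", k, v)
    }, character(1))
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) "." else paste(vals, collapse = ";")
  }, character(1))
  filt <- if ("filter" %in% names(records)) records$filter else rep(".", nrow(records))
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\t%s\t%s\tGT:AD\t0/1:%d,%d",
    records$chrom, records$pos, records$ref, records$alt,
    filt, info, records$ad_ref, records$ad_alt
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a variant tibble
#'
#' Extracts the hard-filter annotations from INFO and the allele fraction
#' from the AD field of the first sample.
#'
#' @param path VCF path.
#' @param sex optional sex label attached to all records.
#' @return Variant tibble as consumed by [hard_filter()].
#' @export
read_vcf <- function(path, sex = NA_character_) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
  out <- tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    vtype = ifelse(nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L, "SNP", "INDEL")
  )
  for (k in VCF_INFO_KEYS) {
    out[[k]] <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = k)))
  }
  ad <- vcfR::extract.gt(v, element = "AD")[, 1]
  ad_split <- strsplit(ad, ",", fixed = TRUE)
  out$ad_ref <- suppressWarnings(as.integer(vapply(ad_split, `[`, character(1), 1)))
  out$ad_alt <- suppressWarnings(as.integer(vapply(ad_split, function(x) {
    if (length(x) >= 2) x[2] else NA_character_
  }, character(1))))
  dp <- out$ad_ref + out$ad_alt
  out$allele_fraction <- ifelse(dp > 0, out$ad_alt / dp, NA_real_)
  out$sex <- sex
  dplyr::arrange(out, .data$chrom, .data$pos)
}

#' Write / read a reference FASTA
#'
#' @param sequences named character vector of sequences.
#' @param path FASTA path.
#' @export
write_fasta <- function(sequences, path) {
  ss <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path, width = 80)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA and CDS features (1-based inclusive coordinates).
#'
#' @param genes gene model tibble from [gene_models()].
#' @param path output path.
#' @param chrom chromosome name for all features.
#' @export
write_gene_models <- function(genes, path, chrom) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gid <- g$name
    lines <- c(lines,
      sprintf("%s\tztrscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
              chrom, g$start + 1L, g$end, g$strand, gid, gid),
      sprintf("%s\tztrscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              chrom, g$start + 1L, g$end, g$strand, gid, gid)
    )
    cds <- g$cds[[1]]
    for (j in seq_len(nrow(cds))) {
      lines <- c(lines,
        sprintf("%s\tztrscan\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s.t1",
                chrom, cds$start[j] + 1L, cds$end[j], g$strand, gid, gid))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' @param path GFF3 with gene/mRNA/CDS features as written by
#'   [write_gene_models()] (CDS linked to genes via `Parent`).
#' @return Gene model tibble.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  genes <- df[df$type == "gene", ]
  cds <- df[df$type == "CDS", ]
  cds$gene <- sub("\\.t1$", "", as.character(cds$Parent))
  gene_models(
    name = genes$ID,
    start = genes$start - 1L,
    end = genes$end,
    strand = as.character(genes$strand),
    cds = lapply(genes$ID, function(g) {
      seg <- cds[cds$gene == g, ]
      seg <- seg[order(seg$start), ]
      tibble::tibble(start = seg$start - 1L, end = seg$end)
    })
  )
}

#' Write all artefacts of a simulation to a directory
#'
#' Writes the reference FASTA, gene GFF3, per-sex depth tables and VCFs,
#' the shared planted variants, and a plain-text truth file.
#'
#' @param sim a `ztr_sim` object.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_sim <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  write_fasta(setNames(sim$reference, sim$layout$chrom_name), p("reference.fa"))
  write_gene_models(sim$layout$genes, p("genes.gff3"), sim$layout$chrom_name)
  for (sex in c("female", "male")) {
    write_depth(simulate_depth(sim, sex), p(sprintf("depth_%s.tsv", sex)))
    write_vcf(simulate_variants(sim, sex), p(sprintf("variants_%s.vcf", sex)),
              sample_name = sex)
  }
  readr::write_tsv(sim$truth$shared_variants, p("truth_variants.tsv"))
  truth <- list(
    chrom = sim$layout$chrom_name,
    chrom_length = sim$layout$chrom_length,
    window_size = sim$layout$window_size,
    seed = sim$params$seed,
    regions = unname(apply(sim$truth$regions, 1, as.list)),
    w_deletions = unname(apply(sim$truth$w_deletions, 1, as.list)),
    window_labels = sim$truth$window_labels$label,
    gene_fates = setNames(as.list(sim$truth$gene_fates$fate),
                          sim$truth$gene_fates$name)
  )
  yaml::write_yaml(truth, p("truth.yaml"))
  invisible(outdir)
}

#' Write window statistics / region calls as TSV
#'
#' @param x window or region tibble.
#' @param path output path.
#' @export
write_windows <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}

#' @rdname write_windows
#' @export
write_regions <- function(x, path) {
  readr::write_tsv(tidy(x), path)
  invisible(path)
}
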