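# Genomic file I/O and the intergenic filtering stage.
#
# All tables exposed to the user are BED-convention 0-based half-open;
# interval arithmetic runs on GRanges (1-based) via gr_from_bed0().

narrowpeak_extra <- c(signalValue = "numeric", pValue = "numeric",
                      qValue = "numeric", peak = "integer")

#' Read an ENCODE narrowPeak (BED6+4) file
#'
#' The summit column (relative offset, column 10) is converted to an
#' absolute position; a missing summit (offset -1) falls back to the
#' interval midpoint. The q-value stays on the -log10 scale of column 9.
#'
#' @param path narrowPeak file (gzip transparent).
#' @param dataset_id identifier attached to every peak.
#' @return 0-based half-open peak data.frame with columns `chrom`, `start`,
#'   `end`, `summit`, `qvalue`, `dataset_id`.
#' @export
read_narrowpeak <- function(path, dataset_id = basename(path)) {
  gr <- rtracklayer::import(path, format = "BED", extraCols = narrowpeak_extra)
  df <- bed0_from_gr(gr)
  off <- df$peak
  summit <- ifelse(is.na(off) | off < 0,
                   df$start + floor((df$end - df$start) / 2),
                   df$start + off)
  data.frame(chrom = df$chrom, start = df$start, end = df$end,
             summit = as.integer(summit), qvalue = df$qValue,
             dataset_id = dataset_id, stringsAsFactors = FALSE)
}

#' Write peaks as narrowPeak
#' @param peaks peak data.frame as returned by [read_narrowpeak()].
#' @param path output file.
#' @export
write_narrowpeak <- function(peaks, path) {
  out <- data.frame(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = if (!is.null(peaks$peak_id)) peaks$peak_id else ".",
    score = 0L, strand = ".",
    signalValue = 0, pValue = -1, qValue = peaks$qvalue,
    peak = peaks$summit - peaks$start
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3/BED6 file into GRanges
#' @param path BED file.
#' @return GRanges.
#' @export
read_bed <- function(path) rtracklayer::import(path, format = "BED")

#' Write GRanges as BED
#' @param gr GRanges.
#' @param path output file.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read transcript features from a GFF3 file
#' @param path GFF3 file.
#' @param types feature types to keep.
#' @return stranded GRanges with `gene_id` metadata where present.
#' @export
read_gff3_transcripts <- function(path, types = c("transcript", "mRNA")) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr[S4Vectors::mcols(gr)$type %in% types]
}

#' Write transcripts as GFF3
#' @param transcripts stranded GRanges with a `gene_id` column.
#' @param path output file.
#' @export
write_gff3_transcripts <- function(transcripts, path) {
  S4Vectors::mcols(transcripts)$type <- "transcript"
  if (is.null(S4Vectors::mcols(transcripts)$ID) &&
      !is.null(S4Vectors::mcols(transcripts)$gene_id))
    S4Vectors::mcols(transcripts)$ID <- S4Vectors::mcols(transcripts)$gene_id
  rtracklayer::export(transcripts, path, format = "gff3")
  invisible(path)
}

#' Build the excluded (non-intergenic) space
#'
#' The mask is the union of every transcript padded by `pad` bp on both
#' sides (clipped at zero) and the blacklist, merged into disjoint
#' intervals. Peaks overlapping this mask by at least one base are not
#' intergenic.
#'
#' @param transcripts GRanges of transcripts.
#' @param blacklist GRanges of blacklisted regions.
#' @param pad padding in bp (default 1000).
#' @return GRanges of merged excluded intervals.
#' @export
build_intergenic_mask <- function(transcripts, blacklist = GenomicRanges::GRanges(),
                                  pad = 1000L) {
  if (length(transcripts)) {
    padded <- GenomicRanges::GRanges(
      seqnames = GenomicRanges::seqnames(transcripts),
      ranges = IRanges::IRanges(
        start = pmax(GenomicRanges::start(transcripts) - pad, 1L),
        end = GenomicRanges::end(transcripts) + pad
      )
    )
  } else {
    padded <- GenomicRanges::GRanges()
  }
  combined <- suppressWarnings(c(padded, GenomicRanges::granges(blacklist)))
  GenomicRanges::reduce(combined)
}

#' Apply the peak-level and dataset-level intergenic filters
#'
#' Removes peaks overlapping the mask by >= 1 bp (the whole peak interval,
#' not just the summit), peaks with -log10 q-value at or below
#' `q_threshold` (column-9 value > 5 is equivalent to q < 1e-5), and then
#' drops entire datasets whose surviving intergenic peak count falls below
#' `min_peaks`.
#'
#' @param peaks peak data.frame (0-based half-open with `summit`, `qvalue`,
#'   `dataset_id`).
#' @param mask GRanges of excluded space from [build_intergenic_mask()].
#' @param q_threshold -log10 q-value threshold (default 5, i.e. q < 1e-5).
#' @param min_peaks minimum surviving peaks per dataset (default 100).
#' @param chrom_names optional character vector of known chromosomes; peaks
#'   on other chromosomes are dropped with a warning.
#' @return list with `peaks` (surviving peaks) and `datasets` (dataset_id,
#'   biotype if present upstream is not carried here, n_intergenic_peaks).
#' @export
filter_dataset_peaks <- function(peaks, mask, q_threshold = 5,
                                 min_peaks = 100L, chrom_names = NULL) {
  if (!is.null(chrom_names)) {
    unknown <- !(peaks$chrom %in% chrom_names)
    if (any(unknown)) {
      warning(sum(unknown), " peak(s) on unknown chromosomes dropped: ",
              paste(unique(peaks$chrom[unknown]), collapse = ", "))
      peaks <- peaks[!unknown, , drop = FALSE]
    }
  }
  keep_q <- peaks$qvalue > q_threshold
  peaks <- peaks[keep_q, , drop = FALSE]
  if (nrow(peaks) && length(mask)) {
    hits <- GenomicRanges::countOverlaps(gr_from_bed0(peaks), mask) > 0
    peaks <- peaks[!hits, , drop = FALSE]
  }
  counts <- table(peaks$dataset_id)
  keep_ds <- names(counts)[counts >= min_peaks]
  peaks <- peaks[peaks$dataset_id %in% keep_ds, , drop = FALSE]
  rownames(peaks) <- NULL
  datasets <- data.frame(
    dataset_id = keep_ds,
    n_intergenic_peaks = as.integer(counts[keep_ds]),
    stringsAsFactors = FALSE
  )
  list(peaks = peaks, datasets = datasets)
}

#' Test which 1-bp points fall inside features
#'
#' Consensus-versus-feature intersections use the 1-bp centroid only, in
#' half-open convention: position p hits `[start, end)` iff
#' start <= p < end.
#'
#' @param points data.frame with `chrom` and `pos` (0-based positions).
#' @param features GRanges.
#' @return logical vector, one per point.
#' @export
intersect_centroids <- function(points, features) {
  if (nrow(points) == 0L) return(logical(0))
  if (length(features) == 0L) return(rep(FALSE, nrow(points)))
  pts <- GenomicRanges::GRanges(
    seqnames = points$chrom,
    ranges = IRanges::IRanges(start = points$pos + 1L, width = 1L)
  )
  IRanges::overlapsAny(pts, features)
}

#' Write a full synthetic-study input directory with a manifest
#'
#' Emits one narrowPeak file per dataset, the annotation as GFF3, the
#' blacklist as BED, the count matrix and sample metadata as TSV, the
#' survival table as TSV, the configuration as JSON, and a `manifest.json`
#' listing every file.
#'
#' @param sim output of the simulate_* generators collected in a list with
#'   elements `peaksets`, `annotation`, and optionally `expression`
#'   (counts + sample_meta) and `survival`.
#' @param cfg the [sim_config()] used.
#' @param dir output directory (created if needed).
#' @return the manifest (invisibly).
#' @export
write_simulation <- function(sim, cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (ds in unique(sim$peaksets$peaks$dataset_id)) {
    f <- file.path(dir, paste0(ds, ".narrowPeak"))
    write_narrowpeak(sim$peaksets$peaks[sim$peaksets$peaks$dataset_id == ds, ], f)
    files[[length(files) + 1L]] <- list(path = basename(f),
                                        type = "narrowPeak", dataset = ds)
  }
  meta_f <- file.path(dir, "datasets.tsv")
  utils::write.table(sim$peaksets$datasets, meta_f, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files[[length(files) + 1L]] <- list(path = "datasets.tsv", type = "tsv")
  gff_f <- file.path(dir, "annotation.gff3")
  write_gff3_transcripts(sim$annotation$transcripts, gff_f)
  files[[length(files) + 1L]] <- list(path = "annotation.gff3", type = "gff3")
  bl_f <- file.path(dir, "blacklist.bed")
  write_bed(sim$annotation$blacklist, bl_f)
  files[[length(files) + 1L]] <- list(path = "blacklist.bed", type = "bed")
  if (!is.null(sim$expression)) {
    utils::write.table(sim$expression$counts, file.path(dir, "counts.tsv"),
                       sep = "\t", quote = FALSE)
    utils::write.table(sim$expression$sample_meta,
                       file.path(dir, "samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files[[length(files) + 1L]] <- list(path = "counts.tsv", type = "tsv")
    files[[length(files) + 1L]] <- list(path = "samples.tsv", type = "tsv")
  }
  if (!is.null(sim$survival)) {
    utils::write.table(sim$survival, file.path(dir, "survival.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files[[length(files) + 1L]] <- list(path = "survival.tsv", type = "tsv")
  }
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  files[[length(files) + 1L]] <- list(path = "config.json", type = "json")
  manifest <- list(generator = "peakAtlas::write_simulation", files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
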