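#' Read a Bismark-style coverage file
#'
#' Parses a per-sample CpG count file in the six-column coverage dialect
#' produced by the Bismark methylation extractor: chromosome, start (1-based),
#' end, methylation percentage, methylated read count, unmethylated read
#' count. The percentage column is advisory only: counts are authoritative,
#' but the percentage is validated to within 0.5 of `100 * meth / total`.
#'
#' @param path Path to a tab-separated coverage file (no header).
#' @param min_total Minimum total read count (methylated + unmethylated) a
#'   site must reach to be retained. Default 1, i.e. any covered site.
#' @return A `data.frame` with columns `chrom` (character), `pos` (integer,
#'   1-based), `meth` and `total` (integer read counts), sorted by
#'   (chrom, pos).
#' @examples
#' f <- tempfile(fileext = ".cov")
#' writeLines("chr1\t100\t100\t75\t3\t1", f)
#' read_bismark_coverage(f)
#' @export
read_bismark_coverage <- function(path, min_total = 1L) {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", colClasses = list(
      character = 1), fill = FALSE, data.table = TRUE),
    error = function(e) stop("failed to parse coverage file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(dt) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      meth = integer(0), total = integer(0)))
  }
  if (ncol(dt) != 6L) {
    stop("coverage file '", path, "' has ", ncol(dt),
         " columns; expected 6 (chrom, start, end, pct, meth, unmeth)")
  }
  names(dt) <- c("chrom", "start", "end", "pct", "n_meth", "n_unmeth")
  for (col in c("start", "end", "pct", "n_meth", "n_unmeth")) {
    v <- suppressWarnings(as.numeric(dt[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop("malformed line ", bad[1L], " in '", path,
           "': non-numeric value in column ", col)
    }
    dt[[col]] <- v
  }
  neg <- which(dt$n_meth < 0 | dt$n_unmeth < 0)
  if (length(neg)) {
    stop("malformed line ", neg[1L], " in '", path, "': negative read count")
  }
  if (any(dt$start < 1)) {
    stop("malformed line ", which(dt$start < 1)[1L], " in '", path,
         "': position < 1")
  }
  dup <- which(duplicated(paste(dt$chrom, dt$start)))
  if (length(dup)) {
    stop("duplicate site (", dt$chrom[dup[1L]], ", ", dt$start[dup[1L]],
         ") at line ", dup[1L], " in '", path, "'")
  }
  meth  <- as.integer(round(dt$n_meth))
  total <- as.integer(round(dt$n_meth + dt$n_unmeth))
  pos_tot <- total > 0L
  pct_dev <- abs(dt$pct[pos_tot] - 100 * meth[pos_tot] / total[pos_tot])
  if (any(pct_dev > 0.5)) {
    i <- which(pos_tot)[which(pct_dev > 0.5)[1L]]
    stop("line ", i, " in '", path, "': percentage column (", dt$pct[i],
         ") disagrees with counts (", meth[i], "/", total[i], ")")
  }
  keep <- total >= as.integer(min_total)
  out <- data.frame(chrom = dt$chrom[keep], pos = as.integer(dt$start[keep]),
                    meth = meth[keep], total = total[keep],
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Write a single-sample site table in the coverage dialect
#'
#' Inverse of [read_bismark_coverage()]; used by the simulator and for
#' round-trip serialization of a [MethylationMatrix].
#'
#' @param tab `data.frame` with `chrom`, `pos`, `meth`, `total`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bismark_coverage <- function(tab, path) {
  stopifnot(all(c("chrom", "pos", "meth", "total") %in% names(tab)))
  pct <- ifelse(tab$total > 0, 100 * tab$meth / tab$total, 0)
  out <- data.table::data.table(
    chrom = tab$chrom, start = tab$pos, end = tab$pos,
    pct = pct, n_meth = tab$meth, n_unmeth = tab$total - tab$meth)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' @param path TSV with header columns `sample_id`, `species`, `age_years`
#'   and optionally `age_group`.
#' @return `data.frame` with one row per sample; `age_years` numeric.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample_id", "species", "age_years")
  miss <- setdiff(req, names(md))
  if (length(miss)) stop("sample metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  age <- suppressWarnings(as.numeric(md$age_years))
  if (any(!is.finite(age))) {
    stop("non-numeric age_years for sample(s): ",
         paste(md$sample_id[!is.finite(age)], collapse = ", "))
  }
  md$age_years <- age
  if (anyDuplicated(md$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  }
  if (!"age_group" %in% names(md)) md$age_group <- NA_character_
  md[, c("sample_id", "species", "age_years", "age_group")]
}

#' Collapse CpG dinucleotide strands
#'
#' Sums read counts of records at adjacent positions (pos, pos + 1) on the
#' same chromosome — the two strands of one CpG dinucleotide — assigning the
#' merged record to the lower coordinate. Records without a partner are kept
#' unchanged.
#'
#' @param tab Single-sample site table (`chrom`, `pos`, `meth`, `total`).
#' @return Collapsed site table, sorted by (chrom, pos).
#' @export
collapse_strands <- function(tab) {
  tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
  n <- nrow(tab)
  if (n == 0L) return(tab)
  # runs of consecutive positions on one chromosome; within a run, greedy
  # left-to-right pairing = records at even offset anchor the pair
  new_run <- c(TRUE, !(tab$chrom[-1L] == tab$chrom[-n] &
                         tab$pos[-1L] == tab$pos[-n] + 1L))
  run <- cumsum(new_run)
  offset <- stats::ave(seq_len(n), run, FUN = function(i) seq_along(i) - 1L)
  anchor_pos <- tab$pos - offset %% 2L
  anchor <- paste0(tab$chrom, ":", anchor_pos)
  meth  <- rowsum(tab$meth,  anchor, reorder = FALSE)
  total <- rowsum(tab$total, anchor, reorder = FALSE)
  first <- !duplicated(anchor)
  out <- data.frame(chrom = tab$chrom[first],
                    pos = anchor_pos[first],
                    meth = as.integer(meth[, 1L]),
                    total = as.integer(total[, 1L]),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Merge per-sample site tables on the common covered sites
#'
#' Restricts to the exact intersection of CpG sites covered in every sample
#' and assembles the methylated / total read-count matrices. Only sites
#' covered in all samples are used further downstream.
#'
#' @param tables Named list of single-sample site tables (names are sample
#'   ids), as returned by [read_bismark_coverage()].
#' @param metadata Sample metadata `data.frame` (see
#'   [read_sample_metadata()]); column order of the result follows the
#'   metadata row order.
#' @return A `MethylationMatrix`: list with `sites` (`data.frame` of `chrom`,
#'   `pos`, sorted), `samples`, `meth` and `total` (sites x samples integer
#'   matrices), and `metadata`.
#' @export
merge_common_sites <- function(tables, metadata) {
  if (length(tables) < 2L) stop("need at least 2 samples to merge")
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stop("'tables' must be a named list (names = sample ids)")
  }
  missing_tab <- setdiff(metadata$sample_id, names(tables))
  if (length(missing_tab)) {
    stop("metadata sample(s) with no coverage table: ",
         paste(missing_tab, collapse = ", "))
  }
  tables <- tables[metadata$sample_id]
  keys <- lapply(tables, function(t) paste0(t$chrom, ":", t$pos))
  common <- Reduce(intersect, keys)
  if (length(common) == 0L) stop("no CpG site is covered in all samples")
  ref <- tables[[1L]]
  idx0 <- match(common, keys[[1L]])
  ord <- order(ref$chrom[idx0], ref$pos[idx0])
  common <- common[ord]
  sites <- data.frame(chrom = ref$chrom[idx0][ord], pos = ref$pos[idx0][ord],
                      stringsAsFactors = FALSE)
  meth  <- matrix(0L, nrow = length(common), ncol = length(tables))
  total <- matrix(0L, nrow = length(common), ncol = length(tables))
  for (j in seq_along(tables)) {
    i <- match(common, keys[[j]])
    meth[, j]  <- tables[[j]]$meth[i]
    total[, j] <- tables[[j]]$total[i]
  }
  colnames(meth) <- colnames(total) <- metadata$sample_id
  rownames(meth) <- rownames(total) <- common
  structure(list(sites = sites, samples = metadata$sample_id,
                 meth = meth, total = total, metadata = metadata),
            class = "MethylationMatrix")
}

#' @export
print.MethylationMatrix <- function(x, ...) {
  cat("MethylationMatrix:", nrow(x$sites), "CpG sites x",
      length(x$samples), "samples\n")
  cat("  chromosomes:", length(unique(x$sites$chrom)),
      " median total coverage:", stats::median(x$total), "\n")
  invisible(x)
}

#' Write a MethylationMatrix back to per-sample coverage files
#'
#' @param mm A `MethylationMatrix`.
#' @param dir Output directory; one `<sample_id>.cov` file per sample.
#' @return Invisibly, the vector of file paths.
#' @export
write_methylation_matrix <- function(mm, dir) {
  stopifnot(inherits(mm, "MethylationMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(mm$samples))
  for (j in seq_along(mm$samples)) {
    tab <- data.frame(chrom = mm$sites$chrom, pos = mm$sites$pos,
                      meth = mm$meth[, j], total = mm$total[, j])
    paths[j] <- file.path(dir, paste0(mm$samples[j], ".cov"))
    write_bismark_coverage(tab, paths[j])
  }
  invisible(paths)
}
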