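#' Read a gene expression matrix from tab-separated text
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; remaining cells are log2-scale intensities. Duplicate gene
#' rows (multiple probes mapping to one symbol) are collapsed by their mean,
#' and the collapse is recorded in the `"collapsed"` attribute.
#'
#' @param path Path to a TSV file (lines starting with `#` are skipped).
#' @return A numeric matrix, genes in rows (rownames) and samples in columns
#'   (colnames), with attribute `collapsed` giving the number of duplicate
#'   gene rows that were merged.
#' @export
read_expression <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2L) stop("expression file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 2L) stop("malformed header (need gene column + >=1 sample): ", path)
  sample_ids <- trimws(header[-1L])
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ID(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  body <- fields[-1L]
  nf <- lengths(body)
  if (any(nf != length(header)))
    stop("row ", which(nf != length(header))[1L] + 1L, " has ", nf[nf != length(header)][1L],
         " fields, expected ", length(header))
  genes <- trimws(vapply(body, `[[`, "", 1L))
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(sample_ids))
  for (j in seq_along(sample_ids)) {
    raw <- vapply(body, `[[`, "", j + 1L)
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric value '", raw[bad[1L]], "' for gene '", genes[bad[1L]],
           "', sample '", sample_ids[j], "'")
    vals[, j] <- v
  }
  n_dup <- sum(duplicated(genes))
  if (n_dup > 0L) {
    vals <- rowsum(vals, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- unique(genes)
  }
  dimnames(vals) <- list(genes, sample_ids)
  attr(vals, "collapsed") <- n_dup
  vals
}

#' Write an expression matrix as TSV
#'
#' @param m Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param comment Optional character vector written as `#`-prefixed header
#'   lines (provenance: pipeline version, seed, parameters).
#' @export
write_expression <- function(m, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c("gene", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1L, function(r) paste(format(r, digits = 17, scientific = FALSE, trim = TRUE), collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Read transcription-factor target sets in GMT format
#'
#' Standard GMT: one set per line, `name TAB description TAB gene1 TAB ...`.
#' Targets are deduplicated preserving first occurrence. Gene tokens may
#' carry a trailing `+` or `-` marking the direction the target is expected
#' to move when the regulator is activated; when `directions = TRUE` the
#' suffix is stripped and recorded.
#'
#' @param path Path to a GMT file.
#' @param directions Parse trailing `+`/`-` direction suffixes (default TRUE;
#'   genes without a suffix are kept undirectioned).
#' @return Named list of character vectors (regulator -> target genes), with
#'   attribute `directions`: a list, per set, of named character vectors
#'   (`"up"`/`"down"`) for the targets that carried a suffix.
#' @export
read_gmt <- function(path, directions = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no gene sets in ", path)
  sets <- list()
  dirs <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    f <- trimws(f)
    if (length(f) < 3L)
      stop("GMT line ", i, " has ", length(f), " fields; need name, description, >=1 gene")
    name <- f[1L]
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    dir_vec <- character(0)
    if (directions) {
      has_suffix <- grepl("[+-]$", genes)
      if (any(has_suffix)) {
        suf <- substring(genes[has_suffix], nchar(genes[has_suffix]))
        stripped <- sub("[+-]$", "", genes[has_suffix])
        dir_vec <- ifelse(suf == "+", "up", "down")
        names(dir_vec) <- stripped
        genes[has_suffix] <- stripped
      }
    }
    genes <- genes[!duplicated(genes)]
    if (!length(genes)) stop("GMT line ", i, " (", name, ") has no genes")
    if (name %in% names(sets)) stop("duplicate set name '", name, "' at line ", i)
    sets[[name]] <- genes
    dirs[[name]] <- dir_vec[!duplicated(names(dir_vec))]
  }
  attr(sets, "directions") <- dirs
  sets
}

#' Write a gene set collection as GMT
#'
#' Direction annotations (attribute `directions`, as produced by [read_gmt()]
#' or [simulate_cohort()]) are emitted as `+`/`-` suffixes on gene tokens.
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  dirs <- attr(sets, "directions")
  lines <- vapply(names(sets), function(nm) {
    genes <- sets[[nm]]
    d <- dirs[[nm]]
    if (length(d)) {
      suf <- ifelse(genes %in% names(d),
                    ifelse(d[genes] == "up", "+", "-"), "")
      genes <- paste0(genes, suf)
    }
    paste(c(nm, "na", genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

.group_levels <- c("MDD", "nonMDD")
.timepoint_levels <- c("baseline", "post")

#' Read and validate a cohort design table
#'
#' @param path Delimited text (TSV or CSV, sniffed from the header line) with
#'   required columns `patient_id`, `group`, `timepoint`, `madrs` and optional
#'   `sample_id`, `age`, `sex`, `bmi`. `group` must be `MDD`/`nonMDD`,
#'   `timepoint` must be `baseline`/`post`.
#' @return A validated data frame (see [validate_design()]); `sample_id` is
#'   constructed as `patient_id.timepoint` when absent.
#' @export
read_design <- function(path) {
  lines <- readLines(path, n = 50L)
  first <- lines[!startsWith(lines, "#")][1L]
  if (is.na(first)) stop("no data in design file: ", path)
  sep <- if (grepl("\t", first)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                         stringsAsFactors = FALSE)
  validate_design(d)
}

#' Validate a cohort design data frame
#'
#' Checks the paired pre/post contract: factor levels, uniqueness of
#' (patient, timepoint), and that every post-surgery sample has a baseline
#' partner (patients may drop out after baseline, never the reverse).
#'
#' @param d Data frame with columns `patient_id`, `group`, `timepoint`,
#'   `madrs` (plus optional `sample_id`, `age`, `sex`, `bmi`).
#' @return The design with `group`/`timepoint` as factors, invisibly checked.
#' @export
validate_design <- function(d) {
  required <- c("patient_id", "group", "timepoint", "madrs")
  missing <- setdiff(required, names(d))
  if (length(missing)) stop("design missing column(s): ", paste(missing, collapse = ", "))
  bad_grp <- setdiff(unique(as.character(d$group)), .group_levels)
  if (length(bad_grp))
    stop("unknown group level(s) ", paste(bad_grp, collapse = ", "),
         "; allowed: ", paste(.group_levels, collapse = ", "))
  bad_tp <- setdiff(unique(as.character(d$timepoint)), .timepoint_levels)
  if (length(bad_tp))
    stop("unknown timepoint level(s) ", paste(bad_tp, collapse = ", "),
         "; allowed: ", paste(.timepoint_levels, collapse = ", "))
  key <- paste(d$patient_id, d$timepoint)
  if (anyDuplicated(key))
    stop("duplicated (patient, timepoint): ", key[duplicated(key)][1L])
  post_pat <- d$patient_id[d$timepoint == "post"]
  base_pat <- d$patient_id[d$timepoint == "baseline"]
  orphan <- setdiff(post_pat, base_pat)
  if (length(orphan))
    stop("post-surgery sample(s) without baseline: ", paste(orphan, collapse = ", "))
  if (any(!is.na(d$madrs) & d$madrs < 0)) stop("negative MADRS score")
  d$group <- factor(as.character(d$group), levels = .group_levels)
  d$timepoint <- factor(as.character(d$timepoint), levels = .timepoint_levels)
  if (is.null(d$sample_id)) d$sample_id <- paste(d$patient_id, d$timepoint, sep = ".")
  if (anyDuplicated(d$sample_id)) stop("duplicate sample_id")
  d
}

#' Number of patients lost to follow-up in a design
#' @param d Validated design.
#' @return Integer count of baseline patients with no post-surgery sample.
#' @export
n_dropouts <- function(d) {
  length(setdiff(d$patient_id[d$timepoint == "baseline"],
                 d$patient_id[d$timepoint == "post"]))
}

#' Write a design table as TSV
#' @param d Design data frame.
#' @param path Output path.
#' @param comment Optional `#`-prefixed provenance lines.
#' @export
write_design <- function(d, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a result table as TSV with provenance header
#' @param d Data frame.
#' @param path Output path.
#' @param comment Optional `#`-prefixed provenance lines.
#' @export
write_table <- function(d, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
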