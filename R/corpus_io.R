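# Foci corpus I/O, validation and Table-2-style summaries.
#
# A corpus is the clustering unit collection: one record per experiment
# (contrast x sample), each holding its activation foci in MNI mm plus the
# manually annotated phenotype metadata.  Effect direction (hypo/hyper) is
# deliberately not represented: foci are pooled into one aberrant-activation
# map per experiment.

DIAGNOSES    <- c("ADHD", "CD_ODD", "ANX", "DEP", "OTHER")
TASK_DOMAINS <- c("cognitive", "response_inhibition", "attention", "emotion")
VALENCES     <- c("positive", "negative", "both", "none")

#' Construct an experiment record
#'
#' @param study_id,experiment_id identifiers; `experiment_id` must be unique
#'   within a corpus.
#' @param foci n x 3 numeric matrix of MNI mm coordinates (>= 1 row).
#' @param n_cases,n_controls sample sizes (cases >= 1, controls >= 0).
#' @param diagnosis one of ADHD, CD_ODD, ANX, DEP, OTHER (single label).
#' @param task_domain character vector drawn from cognitive,
#'   response_inhibition, attention, emotion.
#' @param valence one of positive, negative, both, none.
#' @param medication_naive logical or NA (unknown).
#' @param pct_boys percent boys in the case sample, `[0, 100]` or NA.
#' @return an `experiment_record`.
#' @export
experiment_record <- function(study_id, experiment_id, foci, n_cases,
                              n_controls = 0L, diagnosis = "OTHER",
                              task_domain = "cognitive", valence = "none",
                              medication_naive = NA, pct_boys = NA_real_) {
  foci <- rbind_coords(foci)
  if (nrow(foci) < 1L) stop("experiment ", experiment_id, " has no foci")
  if (any(!is.finite(foci))) stop("non-finite focus coordinate in ",
                                  experiment_id)
  if (!is.numeric(n_cases) || n_cases < 1) stop("n_cases must be >= 1")
  if (n_controls < 0) stop("n_controls must be >= 0")
  diagnosis <- match.arg(diagnosis, DIAGNOSES)
  task_domain <- unique(vapply(task_domain, match.arg, "", TASK_DOMAINS))
  valence <- match.arg(valence, VALENCES)
  if (!is.na(pct_boys) && (pct_boys < 0 || pct_boys > 100))
    stop("pct_boys outside [0, 100] in ", experiment_id)
  dimnames(foci) <- list(NULL, c("x", "y", "z"))
  structure(list(
    study_id = as.character(study_id),
    experiment_id = as.character(experiment_id),
    foci = foci, n_cases = as.integer(n_cases),
    n_controls = as.integer(n_controls), diagnosis = diagnosis,
    task_domain = task_domain, valence = valence,
    medication_naive = as.logical(medication_naive),
    pct_boys = as.numeric(pct_boys)
  ), class = "experiment_record")
}

#' Construct a corpus from experiment records
#'
#' @param experiments list of [experiment_record()]s.
#' @param provenance free-text provenance note.
#' @return a `corpus`.
#' @export
corpus <- function(experiments, provenance = "") {
  ids <- vapply(experiments, `[[`, "", "experiment_id")
  if (anyDuplicated(ids))
    stop("duplicate experiment_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(experiments) <- ids
  structure(list(experiments = experiments, provenance = provenance),
            class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  nf <- sum(vapply(x$experiments, function(e) nrow(e$foci), 0L))
  cat("corpus: ", length(x$experiments), " experiments, ", nf, " foci\n",
      sep = "")
  invisible(x)
}

#' @export
length.corpus <- function(x) length(x$experiments)

corpus_ids <- function(corp) names(corp$experiments)

read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  read.delim(path, sep = sep, stringsAsFactors = FALSE)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("schema error in ", what, ": missing column(s) ",
         paste(missing, collapse = ", "))
}

parse_logical_na <- function(x) {
  out <- rep(NA, length(x))
  out[tolower(x) %in% c("true", "t", "1", "yes")] <- TRUE
  out[tolower(x) %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Read a foci corpus from delimited tables
#'
#' The foci table has one row per focus (`study_id`, `experiment_id`, `x`,
#' `y`, `z`, `space`); the metadata table one row per experiment
#' (`experiment_id`, `study_id`, `n_cases`, `n_controls`, `diagnosis`,
#' `task_domain` -- semicolon-separated, `valence`, `medication_naive`,
#' `pct_boys`).  Comma- and tab-separated files are both accepted.
#' Talairach rows are converted to MNI on load and the conversion count is
#' reported.
#'
#' @param foci_table_path,metadata_table_path paths to the two tables.
#' @param tal_method Talairach conversion, see [tal_to_mni_xyz()].
#' @return a validated `corpus` (all foci in MNI space).
#' @export
read_corpus <- function(foci_table_path, metadata_table_path,
                        tal_method = "lancaster") {
  foci <- read_table_auto(foci_table_path)
  meta <- read_table_auto(metadata_table_path)
  require_columns(foci, c("study_id", "experiment_id", "x", "y", "z", "space"),
                  "foci table")
  require_columns(meta, c("experiment_id", "study_id", "n_cases", "n_controls",
                          "diagnosis", "task_domain", "valence",
                          "medication_naive", "pct_boys"), "metadata table")
  for (col in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(foci[[col]]))
    bad <- which(is.na(v) & !is.na(foci[[col]]))
    if (length(bad))
      stop("parse error: non-numeric coordinate '", foci[[col]][bad[1]],
           "' in column ", col, ", foci table row ", bad[1])
    foci[[col]] <- v
  }
  orphan <- setdiff(unique(foci$experiment_id), meta$experiment_id)
  if (length(orphan))
    stop("linkage error: experiment(s) in foci table absent from metadata: ",
         paste(orphan, collapse = ", "))

  n_converted <- 0L
  recs <- lapply(seq_len(nrow(meta)), function(i) {
    row <- meta[i, ]
    f <- foci[foci$experiment_id == row$experiment_id, , drop = FALSE]
    if (nrow(f) == 0L)
      stop("linkage error: experiment ", row$experiment_id,
           " has no foci rows")
    xyz <- as.matrix(f[, c("x", "y", "z")])
    is_tal <- f$space == "Talairach"
    if (any(!f$space %in% c("MNI", "Talairach")))
      stop("unknown space value in foci table: ",
           paste(unique(setdiff(f$space, c("MNI", "Talairach"))),
                 collapse = ", "))
    if (any(is_tal)) {
      xyz[is_tal, ] <- tal_to_mni_xyz(xyz[is_tal, , drop = FALSE],
                                      method = tal_method)
      n_converted <<- n_converted + sum(is_tal)
    }
    experiment_record(
      study_id = row$study_id, experiment_id = row$experiment_id,
      foci = xyz, n_cases = row$n_cases, n_controls = row$n_controls,
      diagnosis = row$diagnosis,
      task_domain = strsplit(as.character(row$task_domain), ";")[[1]],
      valence = row$valence,
      medication_naive = parse_logical_na(as.character(row$medication_naive)),
      pct_boys = suppressWarnings(as.numeric(row$pct_boys)))
  })
  message(n_converted, " foci converted from Talairach to MNI (",
          tal_method, ")")
  corpus(recs, provenance = paste0("read_corpus(", basename(foci_table_path),
                                   ", ", basename(metadata_table_path),
                                   "); tal_method=", tal_method))
}

#' Write a corpus back to the delimited-table pair
#'
#' Inverse of [read_corpus()]; re-reading the written pair reproduces the
#' corpus field-for-field (all spaces written as MNI).
#'
#' @param corp a `corpus`.
#' @param foci_table_path,metadata_table_path output paths (`.csv`).
#' @return invisibly, the two paths.
#' @export
write_corpus <- function(corp, foci_table_path, metadata_table_path) {
  foci <- do.call(rbind, lapply(corp$experiments, function(e) {
    data.frame(study_id = e$study_id, experiment_id = e$experiment_id,
               x = e$foci[, 1], y = e$foci[, 2], z = e$foci[, 3],
               space = "MNI")
  }))
  meta <- do.call(rbind, lapply(corp$experiments, function(e) {
    data.frame(experiment_id = e$experiment_id, study_id = e$study_id,
               n_cases = e$n_cases, n_controls = e$n_controls,
               diagnosis = e$diagnosis,
               task_domain = paste(e$task_domain, collapse = ";"),
               valence = e$valence, medication_naive = e$medication_naive,
               pct_boys = e$pct_boys)
  }))
  write.csv(foci, foci_table_path, row.names = FALSE)
  write.csv(meta, metadata_table_path, row.names = FALSE)
  invisible(c(foci_table_path, metadata_table_path))
}

experiment_flags <- function(e) {
  c(setNames(DIAGNOSES == e$diagnosis, DIAGNOSES),
    setNames(TASK_DOMAINS %in% e$task_domain,
             paste0("task_", TASK_DOMAINS)),
    setNames(c("positive", "negative", "both") == e$valence,
             c("valence_positive", "valence_negative", "valence_both")),
    medication_naive = isTRUE(e$medication_naive),
    mixed_sex = !is.na(e$pct_boys) && e$pct_boys > 0 && e$pct_boys < 100)
}

#' Summarize corpus characteristics overall and per group
#'
#' Counts and percentages of each phenotype characteristic, overall and --
#' when `group_labels` is given -- per group, in the layout of a
#' characteristics table (one column pair per group).  Percentages are
#' count / column total x 100.  Valence rows (positive / negative / both)
#' are exclusive, as are diagnosis rows; task-domain rows may overlap since
#' an experiment can probe several domains.
#'
#' @param corp a `corpus`.
#' @param group_labels optional named vector (experiment_id -> group label)
#'   covering a subset of experiments.
#' @return data.frame with one row per characteristic and `n_*` / `pct_*`
#'   columns for the overall corpus and each group.
#' @export
summarize_corpus <- function(corp, group_labels = NULL) {
  if (length(corp) == 0L) stop("empty corpus")
  flags <- vapply(corp$experiments, experiment_flags,
                  experiment_flags(corp$experiments[[1]]))
  ids <- corpus_ids(corp)
  cols <- list(total = ids)
  if (!is.null(group_labels)) {
    unknown <- setdiff(names(group_labels), ids)
    if (length(unknown))
      stop("group_labels name unknown experiments: ",
           paste(unknown, collapse = ", "))
    for (g in sort(unique(group_labels)))
      cols[[paste0("MAG", g)]] <- names(group_labels)[group_labels == g]
  }
  out <- data.frame(characteristic = rownames(flags))
  for (nm in names(cols)) {
    sub <- flags[, cols[[nm]], drop = FALSE]
    n <- rowSums(sub)
    out[[paste0("n_", nm)]] <- n
    out[[paste0("pct_", nm)]] <- round(100 * n / length(cols[[nm]]), 1)
  }
  out
}
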