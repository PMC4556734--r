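# Text interchange: all matrices round-trip losslessly at 12 significant
# digits through TSV, cohorts through a JSON manifest plus per-subject TSVs.

#' Read / write a numeric matrix as TSV
#'
#' @param m numeric matrix.
#' @param path file path.
#' @param col_names write (and expect) a header row.
#' @return `read_matrix_tsv` returns a numeric matrix; the writer returns
#'   `path` invisibly.
#' @export
write_matrix_tsv <- function(m, path, col_names = TRUE) {
  m <- as.matrix(m)
  out <- apply(m, 2, function(x) sprintf("%.12g", x))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(m))
  colnames(out) <- colnames(m)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = col_names)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path, col_names = TRUE) {
  as.matrix(read.delim(path, header = col_names))
}

#' Write a thresholded network as an edge list
#'
#' Three-column TSV (`node_i`, `node_j`, `weight`) of the retained edges,
#' 0-based node ids in parcellation row order.
#'
#' @param net a `weighted_network`.
#' @param path file path.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "weighted_network"))
  n <- nrow(net$weights)
  ei <- edge_index(n)
  vals <- upper_tri_values(net$weights)
  on_edge <- vals != 0
  df <- data.frame(node_i = ei$i[on_edge] - 1L, node_j = ei$j[on_edge] - 1L,
                   weight = sprintf("%.12g", vals[on_edge]))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a cohort directory
#'
#' Serialises a cohort as a JSON manifest (`manifest.json`: subject ids,
#' groups, condition, file names, design seed) plus per-subject TSVs for
#' the time series (`T x N`), realignment parameters (`T x 6`) and observed
#' nuisance signals (`T x 2`), and the parcellation.  Generating-truth
#' parameters are not serialised: a written cohort is what a scanner would
#' have produced.
#'
#' @param cohort a `cohort`.
#' @param dir directory to create.
#' @return `read_cohort` returns a `cohort` (without `truth`); the writer
#'   returns `dir` invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_parcellation(cohort$parcellation, file.path(dir, "parcellation.tsv"))
  entries <- lapply(cohort$subjects, function(s) {
    base <- s$subject_id
    write_matrix_tsv(s$timeseries, file.path(dir, paste0(base, "_ts.tsv")),
                     col_names = FALSE)
    write_matrix_tsv(s$realignment, file.path(dir, paste0(base, "_rp.tsv")))
    write_matrix_tsv(s$confounds, file.path(dir, paste0(base, "_conf.tsv")))
    list(subject_id = s$subject_id, group = s$group,
         condition = s$condition,
         timeseries = paste0(base, "_ts.tsv"),
         realignment = paste0(base, "_rp.tsv"),
         confounds = paste0(base, "_conf.tsv"))
  })
  manifest <- list(condition = cohort$design$condition %||% "rest",
                   seed = cohort$design$seed %||% NA,
                   parcellation = "parcellation.tsv",
                   subjects = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  parc <- read_parcellation(file.path(dir, manifest$parcellation))
  subjects <- lapply(manifest$subjects, function(e) {
    structure(list(
      subject_id = e$subject_id, group = e$group, condition = e$condition,
      timeseries = unname(read_matrix_tsv(file.path(dir, e$timeseries),
                                          col_names = FALSE)),
      realignment = read_matrix_tsv(file.path(dir, e$realignment)),
      confounds = read_matrix_tsv(file.path(dir, e$confounds)),
      truth = NULL), class = "subject_record")
  })
  structure(list(subjects = subjects, parcellation = parc,
                 design = list(condition = manifest$condition,
                               seed = manifest$seed,
                               n_timepoints = nrow(subjects[[1]]$timeseries))),
            class = "cohort")
}

#' Packaged demographic summary of the reference cohort design
#'
#' Printed per-group summary statistics (mean, sample SD, n = 14) of the
#' matched three-group adolescent cohort the analysis design targets: age,
#' full-scale / verbal / performance IQ, Autism-Spectrum Quotient and
#' social-communication score.  Feed rows to [anova_from_summary()] to
#' reconstruct the matching F tests.
#'
#' @return data frame with columns `measure`, `group`, `mean`, `sd`, `n`.
#' @export
load_demographics <- function() {
  read.delim(system.file("extdata", "demographics_summary.tsv",
                         package = "endoconn", mustWork = TRUE),
             stringsAsFactors = FALSE)
}
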