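#' Read a GMT gene-set file
#'
#' Standard tab-separated gene-set format: one set per line as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to a GMT file.
#' @return Named list of character gene vectors, with the descriptions kept
#'   in the `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short)) {
    stop("GMT parse error: line ", short[1],
         " has fewer than 3 fields (name, description, genes...)", call. = FALSE)
  }
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate signature name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  attr(sets, "descriptions") <- stats::setNames(vapply(fields, `[[`, "", 2L), nm)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character gene vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions (default "na").
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene x sample expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids; every
#' cell must be a non-negative number. Parse failures report the offending
#' gene and sample.
#'
#' @param path Path to a tab-separated expression table.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", row.names = NULL)
  if (ncol(raw) < 2L) stop("expression TSV needs gene id + sample columns", call. = FALSE)
  genes <- raw[[1L]]
  if (anyDuplicated(genes)) {
    stop("duplicate gene id(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "), call. = FALSE)
  }
  vals <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw)))
  )
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = nrow(raw),
                                       dimnames = list(NULL, names(raw)[-1L]))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric expression value at gene '", genes[bad[1, 1]],
         "', sample '", colnames(vals)[bad[1, 2]], "'", call. = FALSE)
  }
  rownames(vals) <- genes
  validate_expression(vals)
}

#' Write an expression matrix to TSV
#'
#' @param expr Numeric gene x sample matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read reference cell-content statistics (type, mean, sd) from TSV
#'
#' @param path Path to a tab-separated table with columns type, mean, sd.
#' @return data.frame with columns `type`, `mean`, `sd`.
#' @export
read_reference_stats <- function(path) {
  ref <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("type", "mean", "sd") %in% names(ref))) {
    stop("reference stats need columns type, mean, sd", call. = FALSE)
  }
  if (anyDuplicated(ref$type)) stop("duplicate reference type(s)", call. = FALSE)
  ref
}

#' Write reference statistics to TSV
#' @param ref data.frame with columns type, mean, sd.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_stats <- function(ref, path) {
  utils::write.table(ref[, c("type", "mean", "sd")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an IIS model to JSON
#'
#' Serialises the canonical coefficients together with the direction sets
#' and thresholds needed to apply the model elsewhere.
#'
#' @param model An `iis_model`.
#' @param path Output path.
#' @param dirs Optional `iis_directions` to embed (`up_types`, `down_types`,
#'   `alpha`).
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path, dirs = NULL) {
  obj <- list(a = model$a, b = model$b, c = model$c, method = model$method,
              alpha = if (!is.null(dirs)) dirs$alpha else NA,
              up_types = if (!is.null(dirs)) dirs$up else character(),
              down_types = if (!is.null(dirs)) dirs$down else character())
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read an IIS model from JSON
#' @param path Path written by [write_model_json()].
#' @return List with the `iis_model` under `$model` and (possibly empty)
#'   `$dirs` direction sets.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- structure(list(a = obj$a, b = obj$b, c = obj$c, method = obj$method,
                          positive_class = "CA"), class = "iis_model")
  dirs <- structure(list(up = as.character(obj$up_types),
                         down = as.character(obj$down_types),
                         alpha = obj$alpha),
                    class = "iis_directions")
  list(model = model, dirs = dirs)
}

#' Read a clinical baseline table from CSV
#'
#' Columns: `case`, `age`, `tumour_size_cm` (kept verbatim as strings, e.g.
#' "2 x 1" or "NA"), `histology_grade` (II or III), `nodes_collected`,
#' `nodes_positive`, `regional_node_metastasis` (Yes/No), `t_stage`,
#' `n_stage`, `operation`.
#'
#' @param path Path to the CSV file.
#' @return Validated data.frame.
#' @export
read_clinical_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # na.strings = "": the literal string "NA" is a verbatim tumour-size entry
  cl <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        colClasses = c(tumour_size_cm = "character"))
  validate_clinical(cl)
}

validate_clinical <- function(cl) {
  need <- c("case", "age", "histology_grade", "nodes_collected",
            "nodes_positive", "regional_node_metastasis")
  miss <- setdiff(need, names(cl))
  if (length(miss)) {
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_grade <- !cl$histology_grade %in% c("II", "III")
  if (any(bad_grade)) {
    stop("unknown histology grade for case(s): ",
         paste(cl$case[bad_grade], collapse = ", "), call. = FALSE)
  }
  bad_nodes <- cl$nodes_positive > cl$nodes_collected
  if (any(bad_nodes)) {
    stop("more positive than collected nodes for case(s): ",
         paste(cl$case[bad_nodes], collapse = ", "), call. = FALSE)
  }
  cl
}

#' The packaged clinical baseline table
#'
#' Loads the clinicopathological baseline table shipped with the package
#' (30 patients; age, tumour dimensions, histology grade, nodal status,
#' TNM stage and operation).
#'
#' @return Validated clinical data.frame.
#' @export
load_clinical_fixture <- function() {
  read_clinical_csv(system.file("extdata", "tnbc_clinical_table2.csv",
                                package = "iiscore", mustWork = TRUE))
}

#' Summarise a clinical baseline table
#'
#' Exact grouped counts by histology grade, regional-node metastasis and
#' T/N stage, plus age summaries (mean/sd and median/IQR).
#'
#' @param clinical Clinical data.frame (see [read_clinical_csv()]).
#' @return List of class `iis_clinical_summary`: `n`, `grade`, `metastasis`,
#'   `t_stage`, `n_stage`, `age`.
#' @export
summarize_cohort <- function(clinical) {
  if (!is.data.frame(clinical) || nrow(clinical) == 0L) {
    stop("clinical table is empty", call. = FALSE)
  }
  clinical <- validate_clinical(clinical)
  age <- clinical$age
  out <- list(
    n = nrow(clinical),
    grade = table(clinical$histology_grade),
    metastasis = table(clinical$regional_node_metastasis),
    t_stage = if ("t_stage" %in% names(clinical)) table(clinical$t_stage),
    n_stage = if ("n_stage" %in% names(clinical)) table(clinical$n_stage),
    age = c(mean = mean(age), sd = stats::sd(age),
            median = stats::median(age),
            q1 = unname(stats::quantile(age, 0.25)),
            q3 = unname(stats::quantile(age, 0.75)))
  )
  class(out) <- "iis_clinical_summary"
  out
}

#' @export
print.iis_clinical_summary <- function(x, ...) {
  cat("Patients:", x$n, "\n")
  cat("Grade:   ", paste(names(x$grade), as.integer(x$grade),
                         sep = "=", collapse = "  "), "\n")
  cat("Regional-node metastasis:",
      paste(names(x$metastasis), as.integer(x$metastasis),
            sep = "=", collapse = "  "), "\n")
  cat(sprintf("Age: mean %.2f (sd %.2f), median %.2f [%.2f, %.2f]\n",
              x$age["mean"], x$age["sd"], x$age["median"],
              x$age["q1"], x$age["q3"]))
  invisible(x)
}

#' Write a synthetic cohort to interchange files
#'
#' Writes `expression.tsv`, `signatures.gmt`, `reference_stats.tsv`,
#' `samples.csv`, `clinical.csv` (outcomes), `truth.json` and a run
#' manifest to a directory.
#'
#' @param cohort An `iis_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_expression_tsv(cohort$expression, p("expression.tsv"))
  write_gmt(cohort$signatures, p("signatures.gmt"),
            descriptions = unname(cohort$categories[names(cohort$signatures)]))
  write_reference_stats(cohort$reference_stats, p("reference_stats.tsv"))
  utils::write.csv(cohort$samples, p("samples.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$outcomes, p("clinical.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(direction = stats::setNames(as.list(cohort$truth$direction),
                                     cohort$truth$type),
         config = cohort$config[setdiff(names(cohort$config), "cell_types")]),
    p("truth.json"), auto_unbox = TRUE, digits = NA)
  write_run_manifest(p("manifest.json"),
                     params = list(seed = cohort$config$seed,
                                   n_pairs = cohort$config$n_pairs),
                     inputs = c(p("expression.tsv"), p("signatures.gmt"),
                                p("reference_stats.tsv"), p("clinical.csv")))
  invisible(dir)
}

#' Write a run manifest with parameters and input hashes
#'
#' @param path Output JSON path.
#' @param params Named list of run parameters.
#' @param inputs Character vector of input file paths to hash (md5).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, params = list(), inputs = character()) {
  hashes <- if (length(inputs)) {
    h <- tools::md5sum(inputs[file.exists(inputs)])
    stats::setNames(as.list(unname(h)), basename(names(h)))
  } else list()
  jsonlite::write_json(list(timestamp = format(Sys.time(), tz = "UTC"),
                            params = params, input_md5 = hashes),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
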