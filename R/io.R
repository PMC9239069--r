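#' Read a delimited count or proportion table
#'
#' Expects a header row of sample IDs and a first column of taxon labels
#' (or the transpose, with `transpose = TRUE`). The delimiter is sniffed
#' from the header (tab or comma). Proportion tables are auto-detected by
#' column sums close to 1.
#'
#' @param path Path to a TSV/CSV file.
#' @param sep Field separator; `NULL` (default) sniffs tab vs comma.
#' @param transpose Set `TRUE` when the file has samples in rows.
#' @return Taxa-by-samples numeric matrix with a logical attribute
#'   `proportions`.
#' @export
read_counts <- function(path, sep = NULL, transpose = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (!nzchar(header)) stop("empty table: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("table needs at least one data row and one sample column",
         call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate row identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(df)[-1L]))
    stop("duplicate column identifiers", call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in the table", call. = FALSE)
  rownames(m) <- ids
  if (transpose) m <- t(m)
  attr(m, "proportions") <- all(abs(colSums(m) - 1) < 1e-6)
  m
}

#' Write a taxa-by-samples matrix as delimited text
#'
#' @param mat Matrix with taxon row names and sample column names.
#' @param path Output path; `.csv` extension selects comma separation,
#'   anything else tab.
#' @export
write_counts <- function(mat, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- data.frame(taxon = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run an end-to-end analysis pipeline
#'
#' Thin orchestration over the package's functions: reads a count table,
#' applies the prevalence filter and multiplicative zero replacement,
#' transforms to CLR and runs the requested analysis. Results are returned
#' as a report list and, when `out_dir` is given, written as JSON (plus
#' newick for trees). Inputs are never mutated; the report carries the
#' exact parameter set and seed used.
#'
#' @param command One of `"shift"`, `"regress"`, `"tree"`, `"pca"`,
#'   `"simulate"`, `"filter"`.
#' @param config Named list of parameters. Common entries: `counts` (path
#'   or taxa-by-samples matrix), `out_dir`, `min_reads`, `min_prevalence`,
#'   `delta`, `seed`, `max_d`, `permutations`; for `regress`: `metadata`
#'   (path or data.frame), `predictor`, `covariates`; for `simulate`:
#'   `mode` (`"disturb"` or `"cohort"`), `d`, `n`, `noise`.
#' @return The report list, invisibly when written to disk.
#' @export
run_pipeline <- function(command = c("shift", "regress", "tree", "pca",
                                     "simulate", "filter"),
                         config = list()) {
  command <- match.arg(command)
  cfg <- utils::modifyList(list(
    min_reads = 2, min_prevalence = 0, delta = 0.65, seed = 1,
    permutations = 999, max_d = 30, mode = "disturb", d = 30, n = 100,
    noise = 0.1), config)
  report <- list(command = command,
                 parameters = cfg[setdiff(names(cfg),
                                          c("counts", "metadata", "out_dir"))],
                 version = as.character(utils::packageVersion("onebalance")))
  message("[onebalance] ", command, " (seed ", cfg$seed, ")")

  load_clr <- function() {
    counts <- cfg$counts
    if (is.character(counts)) counts <- read_counts(counts)
    if (is.null(counts)) stop("`counts` is required for ", command,
                              call. = FALSE)
    if (cfg$min_prevalence > 0)
      counts <- prevalence_filter(counts, cfg$min_reads, cfg$min_prevalence)
    props <- if (isTRUE(attr(counts, "proportions")) && !any(counts == 0))
      counts else zero_replace(counts, cfg$delta)
    list(counts = counts, props = props, clr = clr(props))
  }

  res <- switch(command,
    filter = {
      dat <- load_clr()
      report$taxa_kept <- rownames(dat$counts)
      report$table <- dat$props
      report
    },
    shift = {
      dat <- load_clr()
      shift <- if (ncol(dat$props) == 2L)
        clr(perturbation_between(dat$props[, 1L], dat$props[, 2L]))
      else rowMeans(dat$clr)
      nb <- nearest_balance(shift)
      report$balance <- parse_json(balance_report(nb))
      report
    },
    tree = {
      dat <- load_clr()
      shift <- if (ncol(dat$props) == 2L)
        clr(perturbation_between(dat$props[, 1L], dat$props[, 2L]))
      else rowMeans(dat$clr)
      tr <- nearest_balance_tree(shift, max_d = cfg$max_d)
      report$balances <- lapply(seq_along(tr$elements), function(k)
        list(numerator = tr$elements[[k]]$num,
             denominator = tr$elements[[k]]$den,
             coefficient = tr$coefficients[k], impact = tr$impacts[k]))
      report$newick <- to_newick(tr)
      report
    },
    pca = {
      dat <- load_clr()
      labels <- rownames(dat$props)
      basis <- pivot_basis(labels)
      Y <- ilr(dat$clr, basis)
      pb <- principal_balances(Y, basis = basis)
      report$b1 <- parse_json(balance_report(pb$b1))
      report$b2 <- parse_json(balance_report(pb$b2))
      report$explained <- pb$explained
      report
    },
    regress = {
      dat <- load_clr()
      meta <- cfg$metadata
      if (is.character(meta))
        meta <- utils::read.table(meta, header = TRUE, sep = "\t",
                                  check.names = FALSE)
      if (is.null(meta) || is.null(cfg$predictor))
        stop("`metadata` and `predictor` are required for regress",
             call. = FALSE)
      labels <- rownames(dat$props)
      basis <- pivot_basis(labels)
      Y <- ilr(dat$clr, basis)
      x <- meta[[cfg$predictor]]
      Z <- if (length(cfg$covariates))
        as.matrix(meta[, cfg$covariates, drop = FALSE]) else NULL
      design <- sb_design(Y, x, Z, basis = basis, labels = labels)
      fit <- fit_single_balance(design)
      perm <- orthogonal_complement_test(design, fit,
                                         n_permutations = cfg$permutations,
                                         seed = cfg$seed)
      report$balance <- parse_json(balance_report(fit$balance))
      report$impact <- fit$impact
      report$r_squared <- fit$r_squared
      report$p_orthogonal <- perm$p_value
      if (length(unique(x)) == 2L)
        report$auc <- classify_by_balance(fit, Y, truth = x)$auc
      report
    },
    simulate = {
      if (cfg$mode == "disturb") {
        base <- simulate_base_composition(cfg$d, seed = cfg$seed)
        stats_df <- noise_recovery_stats(base$basis, cfg$noise,
                                         replicates = cfg$n, seed = cfg$seed)
        report$mean_accuracy <- mean(stats_df$accuracy)
        report$stats <- stats_df
      } else {
        sim <- simulate_case_control(D = cfg$d, n_per_group = cfg$n,
                                     seed = cfg$seed)
        report$ground_truth <- list(numerator = sim$element$num,
                                    denominator = sim$element$den,
                                    coefficient = sim$coefficient,
                                    sigma2 = sim$sigma2)
        report$data <- sim$Y
        report$labels_x <- sim$x
      }
      report
    })

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    json <- res[setdiff(names(res), c("table", "data", "stats"))]
    jsonlite::write_json(json, file.path(cfg$out_dir,
                                         paste0(command, "_report.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(res$table))
      write_counts(res$table, file.path(cfg$out_dir, "filtered.tsv"))
    if (!is.null(res$newick))
      writeLines(res$newick, file.path(cfg$out_dir, "tree.nwk"))
    return(invisible(res))
  }
  res
}

parse_json <- function(txt) jsonlite::fromJSON(txt, simplifyVector = TRUE)
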