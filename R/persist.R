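#' Persist and reload a fitted stratum model
#'
#' A fitted `stratum_model` is written as a directory of plain-text files
#' (statistics, SVM support vectors/coefficients, cutoffs, configuration,
#' fit log) with full-precision numbers, so a reloaded model reproduces the
#' original decision function bit-identically.
#'
#' @param model a `stratum_model`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly (`write`); the reloaded `stratum_model` (`read`).
#' @export
write_stratum_model <- function(model, dir) {
  stopifnot(inherits(model, "stratum_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  num <- function(x) sprintf("%.17g", x)
  kv <- c(
    "schema_version=1",
    paste0("stratum=", model$stats$stratum),
    paste0("n=", model$stats$n),
    paste0("mean=", paste(num(model$stats$mean), collapse = "\t")),
    paste0("sd=", paste(num(model$stats$sd), collapse = "\t")),
    "covariance:",
    apply(model$stats$covariance, 1L, function(r) paste(num(r), collapse = "\t")))
  writeLines(kv, file.path(dir, "statistics.txt"))
  svm <- c(
    "schema_version=1",
    paste0("gamma=", num(model$gamma)),
    paste0("rho=", num(model$rho)),
    paste0("nu=", num(model$config$nu)),
    paste0("coefs=", paste(num(model$coefs), collapse = "\t")),
    "support_vectors:",
    apply(model$sv, 1L, function(r) paste(num(r), collapse = "\t")))
  writeLines(svm, file.path(dir, "svm.txt"))
  cut <- vapply(names(model$cutoffs), function(nm)
    paste0(nm, "=", paste(num(model$cutoffs[[nm]]), collapse = "\t")),
    character(1))
  writeLines(c("schema_version=1", cut), file.path(dir, "cutoffs.txt"))
  cfg <- model$config
  writeLines(c("schema_version=1",
               paste0("nu=", num(cfg$nu)),
               paste0("gamma=", if (identical(cfg$gamma, "auto")) "auto" else num(cfg$gamma)),
               paste0("train_fraction=", num(cfg$train_fraction)),
               paste0("prefilter_percentile=", num(cfg$prefilter_percentile)),
               paste0("seed=", cfg$seed),
               paste0("prefilter_threshold=", num(model$prefilter_threshold))),
             file.path(dir, "config.txt"))
  fl <- model$fit_log
  writeLines(c("schema_version=1",
               vapply(names(fl), function(nm)
                 paste0(nm, "=", num(fl[[nm]])), character(1))),
             file.path(dir, "fitlog.txt"))
  invisible(dir)
}

read_kv <- function(lines) {
  kv <- lines[grepl("=", lines, fixed = TRUE)]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(as.list(vals), keys)
}

read_matrix_block <- function(lines, header) {
  i <- which(lines == header)
  rows <- lines[(i + 1L):length(lines)]
  do.call(rbind, lapply(strsplit(rows, "\t", fixed = TRUE), as.numeric))
}

#' @rdname write_stratum_model
#' @export
read_stratum_model <- function(dir) {
  st_lines <- readLines(file.path(dir, "statistics.txt"))
  st <- read_kv(st_lines)
  num_vec <- function(s) {
    v <- strsplit(s, "\t", fixed = TRUE)[[1L]]
    v[v == "NA"] <- NA_character_
    as.numeric(v)
  }
  sigma <- read_matrix_block(st_lines, "covariance:")
  colnames(sigma) <- rownames(sigma) <- PARAMS
  stats <- structure(
    list(stratum = st$stratum,
         mean = stats::setNames(num_vec(st$mean), PARAMS),
         sd = stats::setNames(num_vec(st$sd), PARAMS),
         covariance = sigma, n = as.integer(st$n)),
    class = "stratum_statistics")
  svm_lines <- readLines(file.path(dir, "svm.txt"))
  sv_kv <- read_kv(svm_lines)
  sv <- read_matrix_block(svm_lines, "support_vectors:")
  cut_kv <- read_kv(readLines(file.path(dir, "cutoffs.txt")))
  cut_kv$schema_version <- NULL
  cutoffs <- structure(lapply(cut_kv, num_vec), class = "static_cutoffs")
  cfg_kv <- read_kv(readLines(file.path(dir, "config.txt")))
  config <- svm_config(
    nu = as.numeric(cfg_kv$nu),
    gamma = if (identical(cfg_kv$gamma, "auto")) "auto" else as.numeric(cfg_kv$gamma),
    train_fraction = as.numeric(cfg_kv$train_fraction),
    prefilter_percentile = as.numeric(cfg_kv$prefilter_percentile),
    seed = as.integer(cfg_kv$seed))
  fl_kv <- read_kv(readLines(file.path(dir, "fitlog.txt")))
  fl_kv$schema_version <- NULL
  structure(
    list(stats = stats, sv = sv, coefs = num_vec(sv_kv$coefs),
         rho = as.numeric(sv_kv$rho), gamma = as.numeric(sv_kv$gamma),
         cutoffs = cutoffs, config = config,
         prefilter_threshold = as.numeric(cfg_kv$prefilter_threshold),
         fit_log = lapply(fl_kv, as.numeric)),
    class = "stratum_model")
}
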