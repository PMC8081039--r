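# Readers/writers with validation, YAML configuration and a JSON-lines run
# log. CSV dialect: comma, dot decimal, UTF-8, header row required; TSV is
# accepted for count matrices. Times are hours, lengths micrometres.

#' Read a typed table from CSV/TSV
#'
#' @param path File path (CSV; TSV accepted for `kind = "counts"`).
#' @param kind One of `"counts"`, `"lengths"`, `"events"`, `"lipids"`.
#' @return For `"counts"`: an integer matrix (gene ids as rownames). For
#'   the others: a validated tibble with the column contract of the
#'   corresponding module (`time_h`/`length_um`; event times; `lipid_id`,
#'   `class`, sample columns).
#' @export
read_table <- function(path, kind = c("counts", "lengths", "events",
                                      "lipids")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  switch(kind,
    counts = {
      ids <- df[[1]]
      if (anyDuplicated(ids)) {
        abort(sprintf("Duplicate gene id: %s", ids[duplicated(ids)][1]))
      }
      m <- as.matrix(df[, -1, drop = FALSE])
      if (!is.numeric(m)) abort("Count columns must be numeric.")
      if (any(is.na(m))) abort("Malformed numeric cell in count matrix.")
      if (any(m < 0)) abort("Negative count encountered.")
      if (any(m != round(m))) abort("Counts must be integers.")
      storage.mode(m) <- "integer"
      rownames(m) <- ids
      m
    },
    lengths = {
      need <- c("animal_id", "time_h", "length_um")
      miss <- setdiff(need, names(df))
      if (length(miss)) abort(sprintf("Missing column(s): %s",
                                      paste(miss, collapse = ", ")))
      if (any(!is.na(df$length_um) & df$length_um <= 0)) {
        abort("length_um must be positive.")
      }
      tibble::as_tibble(df)
    },
    events = {
      need <- c("animal_id", "t_laid_h", "t_hatch_h", "t_first_egg_h")
      miss <- setdiff(need, names(df))
      if (length(miss)) abort(sprintf("Missing column(s): %s",
                                      paste(miss, collapse = ", ")))
      tibble::as_tibble(df)
    },
    lipids = {
      need <- c("lipid_id", "class")
      miss <- setdiff(need, names(df))
      if (length(miss)) abort(sprintf("Missing column(s): %s",
                                      paste(miss, collapse = ", ")))
      if (anyDuplicated(df$lipid_id)) {
        abort(sprintf("Duplicate lipid id: %s",
                      df$lipid_id[duplicated(df$lipid_id)][1]))
      }
      vals <- as.matrix(df[, setdiff(names(df), need), drop = FALSE])
      if (any(is.na(vals))) abort("Malformed numeric cell in lipid table.")
      if (any(vals < 0)) abort("Lipid abundances must be nonnegative.")
      tibble::as_tibble(df)
    }
  )
}

#' Write a table to CSV (counts also as TSV)
#'
#' @param x Tibble/data frame, or a matrix with rownames (written with an
#'   id first column).
#' @param path Output path; `.tsv` switches to tab separation.
#' @param id_col Name for the id column when `x` is a matrix.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, id_col = "gene_id") {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  if (is.matrix(x)) {
    x <- data.frame(setNames(list(rownames(x)), id_col), x,
                    check.names = FALSE)
  }
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a grayscale worm image from TIFF or PNG
#'
#' RGB images are converted to luminance (0.2126 R + 0.7152 G + 0.0722 B)
#' with a message. The pixel size must be supplied explicitly or through a
#' JSON sidecar `<path>.json` with field `px_size_um`; there is no silent
#' default.
#'
#' @param path Image path (`.tif`/`.tiff`/`.png`).
#' @param px_size_um Pixel size in micrometres; if `NULL`, read from the
#'   sidecar.
#' @return A [worm_image()].
#' @export
read_worm_image <- function(path, px_size_um = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (is.null(px_size_um)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      px_size_um <- jsonlite::read_json(sidecar)$px_size_um
    }
  }
  if (is.null(px_size_um)) {
    abort("Pixel size unknown: pass `px_size_um` or provide a JSON sidecar.")
  }
  arr <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(arr)) == 3) {
    message("RGB input converted to luminance.")
    arr <- 0.2126 * arr[, , 1] + 0.7152 * arr[, , 2] + 0.0722 * arr[, , 3]
  }
  worm_image(arr, px_size_um)
}

#' Write a worm image (16-bit TIFF or 8-bit PNG) plus pixel-size sidecar
#'
#' @param image A [worm_image()] with intensities in \[0, 1\].
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_worm_image <- function(image, path) {
  stopifnot(inherits(image, "worm_image"))
  px <- pmin(pmax(image$pixels, 0), 1)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(px, path)
  } else {
    tiff::writeTIFF(px, path, bits.per.sample = 16)
  }
  jsonlite::write_json(list(px_size_um = image$px_size_um),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read and validate a YAML run configuration
#'
#' @param path YAML file with fields `stage`, `inputs`, `output_dir`,
#'   `params` (stage parameters; every stochastic stage needs a `seed`),
#'   `schema_version`.
#' @return A `run_config` list. Unknown top-level keys are rejected.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A list with the same fields as the YAML file.
#' @export
as_run_config <- function(cfg) {
  allowed <- c("stage", "inputs", "output_dir", "params", "schema_version")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (is.null(cfg$stage)) abort("Config needs a `stage`.")
  if (is.null(cfg$output_dir)) abort("Config needs an `output_dir`.")
  cfg$params <- cfg$params %||% list()
  cfg$inputs <- cfg$inputs %||% list()
  cfg$schema_version <- cfg$schema_version %||% 1L
  structure(cfg, class = "run_config")
}

write_run_log <- function(dir, records) {
  path <- file.path(dir, "run_log.jsonl")
  lines <- vapply(records, function(r) {
    jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

stochastic_stages <- c("simulate", "ratio-bootstrap", "effect-size")

#' Run a pipeline stage from a configuration
#'
#' Dispatches on `config$stage` and writes stage outputs plus a JSON-lines
#' run log into `config$output_dir`. Identical config and inputs give
#' byte-identical CSV outputs. Stages: `simulate` (fixture set + truth
#' JSON), `measure-length`, `growth-fit`, `timings`, `ratio-bootstrap`,
#' `effect-size`, `rnaseq-de`, `embed`, `lipids`.
#'
#' @param config A `run_config` (see [read_run_config()]) or bare list.
#' @return Named character vector of output paths, invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- as_run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  if (config$stage %in% stochastic_stages && is.null(p$seed)) {
    abort(sprintf("Stage '%s' is stochastic and needs params$seed.",
                  config$stage))
  }
  out <- list()
  log <- list(list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stage = config$stage,
                   version = as.character(utils::packageVersion("wormdev")),
                   config = unclass(config)))

  emit <- function(name, x, file) {
    path <- file.path(config$output_dir, file)
    if (is.data.frame(x) || is.matrix(x)) write_table(x, path)
    else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
    out[[name]] <<- path
    log[[length(log) + 1]] <<- list(output = name, file = file,
                                    n = if (is.data.frame(x)) nrow(x) else NA)
  }

  switch(config$stage,
    "simulate" = {
      what <- p$what %||% "growth"
      if (what == "growth") {
        sim <- gen_growth_cohort(
          n_animals = p$n_animals %||% 20, seed = p$seed,
          noise_sd = p$noise_sd %||% 0.05
        )
        emit("trajectories", sim$trajectories, "trajectories.csv")
        emit("events", sim$events, "events.csv")
        emit("truth", as.list(sim$truth), "truth.json")
      } else if (what == "worms") {
        batch <- gen_worm_batch(n = p$n %||% 10, seed = p$seed)
        for (i in seq_len(nrow(batch))) {
          f <- file.path(config$output_dir,
                         paste0(batch$worm_id[i], ".png"))
          write_worm_image(batch$image[[i]], f)
        }
        emit("truth", batch[, c("worm_id", "true_length_um")], "truth.csv")
      } else if (what == "counts") {
        sim <- gen_counts(n_genes = p$n_genes %||% 2000,
                          n_per_group = p$n_per_group %||% 5, seed = p$seed)
        emit("counts", sim$counts, "counts.tsv")
        emit("groups", tibble::tibble(sample_id = names(sim$groups),
                                      group = unname(sim$groups)),
             "groups.csv")
        emit("truth", sim$truth[c("de_genes", "size_factors")], "truth.json")
      } else if (what == "lipids") {
        sim <- gen_lipid_table(seed = p$seed)
        emit("lipids", sim$table, "lipids.csv")
        emit("samples", sim$samples, "samples.csv")
        emit("truth", list(affected_lipids = sim$truth$affected_lipids),
             "truth.json")
      } else abort(sprintf("Unknown simulate target '%s'.", what))
    },
    "measure-length" = {
      files <- sort(list.files(config$inputs$images, full.names = TRUE,
                               pattern = "\\.(png|tiff?)$"))
      res <- purrr::map_dfr(files, function(f) {
        m <- measure_worm_length(read_worm_image(f,
                                                 px_size_um = p$px_size_um))
        dplyr::bind_cols(tibble::tibble(file = basename(f)), m)
      })
      emit("lengths", res, "lengths_um.csv")
    },
    "growth-fit" = {
      tr <- read_table(config$inputs$trajectories, "lengths")
      emit("fits", fit_logistic_cohort(tr), "logistic_fits.csv")
    },
    "timings" = {
      ev <- read_table(config$inputs$events, "events")
      emit("timings", extract_timings(ev), "timings_h.csv")
    },
    "ratio-bootstrap" = {
      a <- read_table(config$inputs$group_a, "lengths")
      b <- read_table(config$inputs$group_b, "lengths")
      emit("ratios",
           windowed_ratio_bootstrap(a, b, B = p$B %||% 1000, seed = p$seed),
           "window_ratios.csv")
    },
    "effect-size" = {
      a <- read_table(config$inputs$control, "events")
      b <- read_table(config$inputs$test, "events")
      col <- p$column %||% "generation_h"
      es <- mean_difference(extract_timings(a)[[col]],
                            extract_timings(b)[[col]],
                            B = p$B %||% 5000, seed = p$seed)
      emit("effect", c(as.list(tidy(es)), as.list(glance(es))),
           "effect_size.json")
    },
    "rnaseq-de" = {
      counts <- read_table(config$inputs$counts, "counts")
      sheet <- read.csv(config$inputs$sample_sheet)
      res <- de_analysis(counts[, sheet$sample_id, drop = FALSE],
                         sheet$group,
                         control_level = p$control_level %||% "control",
                         fdr = p$fdr %||% 0.01,
                         min_fold = p$min_fold %||% 2)
      emit("de", res, "de_results.csv")
    },
    "embed" = {
      q <- read_table(config$inputs$counts, "counts")
      ref <- read_table(config$inputs$reference, "counts")
      emb <- embed_on_reference(normalize_counts(q),
                                normalize_counts(ref),
                                k = p$k %||% 10)
      emit("embedding", emb$query_scores, "embedding.csv")
      emit("reference_scores", emb$reference_scores, "reference_scores.csv")
    },
    "lipids" = {
      tab <- read_table(config$inputs$lipids, "lipids")
      sheet <- tibble::as_tibble(read.csv(config$inputs$sample_sheet))
      res <- lipid_pipeline(tab, sheet, fdr = p$fdr %||% 0.05)
      for (nm in names(res$tests)) {
        emit(nm, res$tests[[nm]], paste0("ttest_", nm, ".csv"))
      }
      emit("consistency", res$consistency$lipids, "consistency.csv")
    },
    abort(sprintf("Unknown stage '%s'.", config$stage))
  )
  write_run_log(config$output_dir, log)
  invisible(unlist(out))
}
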