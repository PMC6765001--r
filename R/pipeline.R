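#' Run the expression pipeline end to end
#'
#' Orchestrates the tabular stages (`simulate` -> `deconvolve` -> `enrich`)
#' with per-stage RNG streams derived from the master seed, validates the
#' configuration before anything runs, and writes a manifest recording the
#' package version, seeds, parameter hashes and output checksums, so a
#' fixed-seed run is reproducible file for file.
#'
#' @param config A named list (or path to a JSON file) with elements:
#'   `stages` (subset of `c("simulate", "deconvolve", "enrich")` in order),
#'   `out_dir`, `seed`, and optional per-stage parameter blocks `simulate`
#'   (arguments to [expr_sim_config()]), `deconvolve` (`stringency`, and —
#'   when the simulate stage is not run — `tissue`, `lymphoid`, `calls`,
#'   `markers` paths), `enrich` (`gmt` path, `min_size`, `name_filter`).
#' @return The manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  stages <- config$stages %||% c("simulate", "deconvolve", "enrich")
  bad <- setdiff(stages, c("simulate", "deconvolve", "enrich"))
  if (length(bad)) abort(paste0("unknown stages: ", paste(bad, collapse = ", ")))
  out_dir <- config$out_dir %||% abort("`out_dir` is required.")
  seed <- as.integer(config$seed %||% 1L)

  # validate inputs before any stage runs
  if ("enrich" %in% stages) {
    gmt <- config$enrich$gmt %||% abort("enrich stage needs a `gmt` path.")
    if (!file.exists(gmt)) abort(paste0("GMT file not found: ", gmt))
  }
  if ("deconvolve" %in% stages && !"simulate" %in% stages) {
    for (f in c("tissue", "lymphoid", "calls", "markers")) {
      p <- config$deconvolve[[f]] %||%
        abort(paste0("deconvolve stage needs `", f, "` when not simulating."))
      if (!file.exists(p)) abort(paste0("input not found: ", p))
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage_seed <- function(name) {
    (seed * 1009L + sum(utf8ToInt(name))) %% 2147483647L
  }
  param_hash <- function(params) {
    tf <- tempfile(fileext = ".json")
    on.exit(unlink(tf))
    jsonlite::write_json(params, tf, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    unname(tools::md5sum(tf))
  }
  manifest <- list(package = "thymoscope",
                   version = as.character(utils::packageVersion("thymoscope")),
                   seed = seed, stages = list())
  record <- function(name, params, outputs) {
    manifest$stages[[name]] <<- list(
      seed = stage_seed(name), params_hash = param_hash(params),
      outputs = lapply(outputs, function(f) {
        list(file = basename(f), md5 = unname(tools::md5sum(f)))
      }))
  }

  sim <- NULL
  state <- list()
  for (st in stages) {
    res <- tryCatch({
      if (st == "simulate") {
        params <- config$simulate %||% list()
        params$seed <- stage_seed("simulate")
        cfg <- do.call(expr_sim_config, params)
        sim <- simulate_expression(cfg)
        tp <- file.path(out_dir, "tissue.tsv")
        lp <- file.path(out_dir, "lymphoid.tsv")
        cp <- file.path(out_dir, "calls.tsv")
        mp <- file.path(out_dir, "markers.txt")
        write_signal_tsv(sim$tissue, tp)
        write_signal_tsv(sim$lymphoid, lp)
        write_calls_tsv(sim$calls, cp)
        writeLines(sim$truth$markers, mp)
        state$tissue <- sim$tissue
        state$lymphoid <- sim$lymphoid
        state$calls <- sim$calls
        state$markers <- sim$truth$markers
        record("simulate", params,
               c(tp, paste0(tp, ".samples.tsv"), lp,
                 paste0(lp, ".samples.tsv"), cp, mp))
      } else if (st == "deconvolve") {
        params <- config$deconvolve %||% list()
        if (is.null(state$tissue)) {
          state$tissue <- read_signal_tsv(params$tissue)
          state$lymphoid <- read_signal_tsv(params$lymphoid)
          state$calls <- read_calls_tsv(params$calls)
          state$markers <- readLines(params$markers)
        }
        k <- params$stringency %||% 2.5
        expressed <- detection_filter(state$tissue, state$calls)
        t_expr <- sm_subset_genes(state$tissue, expressed)
        l_expr <- sm_subset_genes(state$lymphoid, expressed)
        tf <- fit_robust_spline(t_expr)
        lf <- fit_robust_spline(l_expr)
        p <- estimate_lymphoid_proportion(state$tissue, state$lymphoid,
                                          state$markers)
        est <- deconvolve_stromal(tf, lf, p)
        est <- quantile_renormalize(est, tf)
        gl <- stromal_gene_list(state$tissue, state$lymphoid, state$markers,
                                k = k)
        dyn <- flag_dynamic_genes(est)
        sp <- file.path(out_dir, "stromal.tsv")
        readr::write_tsv(as_tibble(est$values, rownames = "gene"), sp)
        glp <- file.path(out_dir, "stromal_genes.tsv")
        readr::write_tsv(as_tibble(gl), glp)
        dynp <- file.path(out_dir, "dynamic_genes.tsv")
        readr::write_tsv(dyn, dynp)
        rp <- file.path(out_dir, "deconvolution_report.json")
        jsonlite::write_json(
          list(p = as.list(setNames(p$p, p$day)), stringency = k,
               threshold = attr(gl, "threshold"),
               n_expressed = length(expressed),
               n_floored_negative = est$n_floored),
          rp, auto_unbox = TRUE, digits = NA)
        state$tf <- tf
        state$lf <- lf
        state$est <- est
        record("deconvolve", params, c(sp, glp, dynp, rp))
      } else {
        params <- config$enrich %||% list()
        gmt_df <- read_gmt(params$gmt)
        universe <- rownames(state$tissue$values)
        coll <- gene_set_collection(gmt_df, universe)
        # per-day stromal lists from the per-day tissue:lymphoid ratio
        ratio <- state$tf$fitted / pmax(state$lf$fitted, 1e-12)
        mk <- intersect(state$markers, rownames(ratio))
        mr <- as.vector(ratio[mk, , drop = FALSE])
        thr <- mean(mr) + (params$stringency %||% 2.0) * sd(mr)
        lists <- apply(ratio, 2, function(r) rownames(ratio)[r > thr],
                       simplify = FALSE)
        series <- enrichment_timecourse(
          lists, coll, min_size = params$min_size %||% 10,
          name_filter = params$name_filter %||% NULL)
        ep <- file.path(out_dir, "enrichment.csv")
        readr::write_csv(as_tibble(series), ep)
        record("enrich", params, ep)
      }
      NULL
    }, error = function(e) e)
    if (inherits(res, "error")) {
      manifest$failed_stage <- st
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      abort(paste0("stage '", st, "' failed: ", conditionMessage(res)))
    }
  }
  manifest$completed <- stages
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
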