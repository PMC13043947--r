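# End-to-end benchmark: select reference, normalize every sample with every
# method, evaluate, and aggregate to report tables and R/B-ratio plots.

#' Tile an image into a non-overlapping grid
#'
#' Row-major grid of `tile_size x tile_size` tiles; right/bottom remainders
#' smaller than a tile are dropped (padding would distort histogram and
#' feature statistics).
#'
#' @param img `H x W x 3` RGB array.
#' @param tile_size Tile side in pixels (at least 32).
#' @return A `tile_set`: list with `tiles` (list of RGB arrays), `origins`
#'   (tibble of 0-based `row`, `col` offsets), and `tile_size`. An image
#'   smaller than one tile yields an empty tile set with a warning.
#' @export
#' @examples
#' ts <- tile_image(array(128, dim = c(96, 96, 3)), 32)
#' length(ts$tiles)
tile_image <- function(img, tile_size) {
  assert_rgb(img)
  if (tile_size < 32) {
    rlang::abort("`tile_size` must be at least 32.",
      class = "stainbench_error_invalid_argument"
    )
  }
  d <- dim(img)
  nr <- d[1] %/% tile_size
  nc <- d[2] %/% tile_size
  if (nr == 0L || nc == 0L) {
    rlang::warn(sprintf(
      "Image (%d x %d) is smaller than one %d px tile; empty tile set.",
      d[1], d[2], tile_size
    ))
    return(structure(
      list(
        tiles = list(),
        origins = tibble::tibble(row = integer(), col = integer()),
        tile_size = tile_size
      ),
      class = "tile_set"
    ))
  }
  grid <- expand.grid(
    col = (seq_len(nc) - 1L) * tile_size,
    row = (seq_len(nr) - 1L) * tile_size
  )[, c("row", "col")] # row-major order
  tiles <- purrr::map2(grid$row, grid$col, function(r, c) {
    img[r + seq_len(tile_size), c + seq_len(tile_size), , drop = FALSE]
  })
  structure(
    list(
      tiles = tiles, origins = tibble::as_tibble(grid),
      tile_size = tile_size
    ),
    class = "tile_set"
  )
}

#' Benchmark configuration
#'
#' @param bins Histogram bins per l-alpha-beta channel (default 256).
#' @param tile Tile side for feature clouds (default 128).
#' @param mask_od `NULL` (include background pixels, the default) or an OD
#'   threshold masking histograms to tissue.
#' @param include_reference Score the reference against itself and include
#'   it in aggregates (default `FALSE`, the 65-of-66 convention).
#' @param seed Top-level seed for the run.
#' @param extractor_seed Seed of the default feature extractor weights.
#' @param method_args Named list of per-method argument lists.
#' @return A list of configuration values for [run_benchmark()].
#' @export
benchmark_config <- function(bins = 256, tile = 128, mask_od = NULL,
                             include_reference = FALSE, seed = 17,
                             extractor_seed = 423, method_args = list()) {
  list(
    bins = bins, tile = tile, mask_od = mask_od,
    include_reference = include_reference, seed = seed,
    extractor_seed = extractor_seed, method_args = method_args
  )
}

panel_images <- function(panel) {
  if (inherits(panel, "synthetic_panel")) {
    return(panel$images)
  }
  if (is.character(panel) && length(panel) == 1L) {
    files <- sort(list.files(panel,
      pattern = "\\.(png|tif|tiff)$",
      ignore.case = TRUE, full.names = TRUE
    ))
    if (length(files) == 0L) {
      rlang::abort(sprintf("No PNG/TIFF images found in '%s'.", panel),
        class = "stainbench_error_invalid_argument"
      )
    }
    imgs <- purrr::map(files, read_image)
    names(imgs) <- tools::file_path_sans_ext(basename(files))
    return(imgs)
  }
  if (is.list(panel)) {
    imgs <- panel
    names(imgs) <- names(imgs) %||% sprintf("sample_%02d", seq_along(imgs))
    return(imgs)
  }
  rlang::abort(
    "`panel` must be a directory, a list of images, or a synthetic_panel.",
    class = "stainbench_error_invalid_argument"
  )
}

#' Run the stain-normalization benchmark on a panel
#'
#' Reproduces the comparative analysis shape end to end: selects the
#' reference by the red-to-blue ratio rule, normalizes every other sample
#' with every requested method (whole-image, never patchwise), evaluates
#' each result against the reference (colour metrics, Frechet feature
#' distance) and the original (SSIM), tracks pre-/post-normalization R/B
#' ratios, and aggregates mean/sd per method and metric. A method failure
#' on a sample is recorded in `$errors`, not raised.
#'
#' @param panel Directory of PNG/TIFF images, a named list of RGB arrays,
#'   or a `synthetic_panel`.
#' @param methods Character vector of registered method names.
#' @param config List from [benchmark_config()].
#' @return A `benchmark_report`: list with `records` (per-sample metric
#'   tibble), `aggregates` (mean/sd per method x metric, with a
#'   best-method flag), `rb` (per-sample, per-method ratios before/after),
#'   `errors`, `reference_id`, `ratios` (pre-normalization panel ratios)
#'   and `config`.
#' @export
run_benchmark <- function(panel,
                          methods = c("histmatch", "reinhard", "macenko", "vahadane"),
                          config = benchmark_config()) {
  images <- panel_images(panel)
  if (length(images) < 2L) {
    rlang::abort("A benchmark panel needs at least 2 images.",
      class = "stainbench_error_invalid_argument"
    )
  }
  set.seed(config$seed)
  sel <- select_reference(images)
  ref_id <- sel$ratios$sample_id[sel$index]
  reference <- images[[sel$index]]
  ranges <- lab_ranges(images)
  mask_r <- if (is.null(config$mask_od)) NULL else tissue_mask(reference, config$mask_od)
  ref_hists <- lab_histograms(reference, config$bins, ranges, mask_r)
  ref_feats <- extract_features(reference, config$tile, seed = config$extractor_seed)
  targets <- if (config$include_reference) {
    seq_along(images)
  } else {
    setdiff(seq_along(images), sel$index)
  }
  runs <- tidyr::expand_grid(idx = targets, method = methods)
  errors <- list()
  results <- purrr::pmap(runs, function(idx, method) {
    id <- names(images)[idx]
    res <- tryCatch(
      rlang::exec(
        normalize_stains, images[[idx]], reference, method,
        !!!(config$method_args[[method]] %||% list())
      ),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <<- tibble::tibble(
        sample_id = id, method = method, message = conditionMessage(res)
      )
      return(NULL)
    }
    rec <- evaluate_sample(
      original = images[[idx]], normalized = res$image,
      reference = reference, sample_id = id, method = method,
      bins = config$bins, ranges = ranges, tile = config$tile,
      mask_od = config$mask_od,
      reference_hists = ref_hists, reference_features = ref_feats,
      extractor_seed = config$extractor_seed
    )
    list(
      record = rec,
      rb = tibble::tibble(
        sample_id = id, method = method,
        rb_before = sel$ratios$ratio[idx],
        rb_after = rb_ratio(res$image)
      )
    )
  })
  results <- purrr::compact(results)
  records <- purrr::map_dfr(results, "record")
  rb <- purrr::map_dfr(results, "rb")
  aggregates <- aggregate_records(records)
  structure(
    list(
      records = records, aggregates = aggregates, rb = rb,
      errors = dplyr::bind_rows(errors),
      reference_id = ref_id, ratios = sel$ratios, config = config,
      methods = methods
    ),
    class = "benchmark_report"
  )
}

.metric_cols <- c("intersection", "pcc", "euclidean", "js", "ssim", "fid")
# Polarity of "best": larger is better for similarity scores, smaller for
# distances/divergences.
.metric_maximize <- c(
  intersection = TRUE, pcc = TRUE, euclidean = FALSE,
  js = FALSE, ssim = TRUE, fid = FALSE
)

aggregate_records <- function(records) {
  long <- tidyr::pivot_longer(records,
    cols = dplyr::all_of(.metric_cols),
    names_to = "metric", values_to = "value"
  )
  agg <- long |>
    dplyr::group_by(.data$method, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = stats::sd(.data$value, na.rm = TRUE),
      n = sum(!is.na(.data$value)),
      .groups = "drop"
    )
  agg |>
    dplyr::group_by(.data$metric) |>
    dplyr::mutate(
      best = ifelse(.metric_maximize[.data$metric],
        .data$mean == max(.data$mean),
        .data$mean == min(.data$mean)
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$metric, .data$method)
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf(
    "<benchmark_report> reference '%s', %d records, methods: %s\n",
    x$reference_id, nrow(x$records), paste(x$methods, collapse = ", ")
  ))
  print(glance(x))
  invisible(x)
}

#' Tidy a benchmark report
#'
#' @param x A `benchmark_report`.
#' @param ... Unused.
#' @return The per-sample metric records as a tibble.
#' @method tidy benchmark_report
#' @export
tidy.benchmark_report <- function(x, ...) x$records

#' @rdname tidy.benchmark_report
#' @return For `glance()`: one row per method with the mean of each metric.
#' @method glance benchmark_report
#' @export
glance.benchmark_report <- function(x, ...) {
  x$aggregates |>
    dplyr::select("method", "metric", "mean") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "mean") |>
    dplyr::select("method", dplyr::any_of(.metric_cols))
}

#' R/B ratio convergence summary
#'
#' Mean absolute deviation of the red-to-blue ratio from 1, before and
#' after normalization, per method. Normalization toward a colour-balanced
#' reference should shrink the deviation for every method.
#'
#' @param report A `benchmark_report`.
#' @return Tibble with `method`, `mad_before`, `mad_after`, `converged`.
#' @export
rb_convergence <- function(report) {
  report$rb |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      mad_before = mean(abs(.data$rb_before - 1)),
      mad_after = mean(abs(.data$rb_after - 1)),
      .groups = "drop"
    ) |>
    dplyr::mutate(converged = .data$mad_after < .data$mad_before)
}

#' Plot R/B ratios before and after normalization
#'
#' The before/after analogue of the panel colour-spread plot: each
#' sample's red-to-blue mean intensity ratio, unnormalized and after each
#' method, with the colour-balanced ratio 1 marked.
#'
#' @param object A `benchmark_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot benchmark_report
#' @export
autoplot.benchmark_report <- function(object, ...) {
  df <- object$rb |>
    tidyr::pivot_longer(c("rb_before", "rb_after"),
      names_to = "stage", values_to = "ratio"
    ) |>
    dplyr::mutate(
      stage = factor(.data$stage, c("rb_before", "rb_after"),
        c("before", "after")
      )
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_id, .data$ratio,
    colour = .data$stage
  )) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(
      x = NULL, y = "red / blue mean intensity ratio",
      title = "R/B ratio convergence under stain normalization"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Write benchmark reports to disk
#'
#' Writes `records.csv` (per-sample metrics), `aggregates.csv` (mean/sd
#' per method and metric with the best method flagged per metric),
#' `rb_ratios.csv`, an R/B convergence plot `rb_ratio.png`, and
#' `run_metadata.json` (reference, methods, seeds and parameters). CSV
#' content is deterministic for a fixed seed.
#'
#' @param report A `benchmark_report`.
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    rlang::abort(sprintf("Cannot create output directory '%s'.", out_dir),
      class = "stainbench_error_io"
    )
  }
  paths <- c(
    records = file.path(out_dir, "records.csv"),
    aggregates = file.path(out_dir, "aggregates.csv"),
    rb = file.path(out_dir, "rb_ratios.csv"),
    plot = file.path(out_dir, "rb_ratio.png"),
    metadata = file.path(out_dir, "run_metadata.json")
  )
  readr::write_csv(report$records, paths["records"])
  readr::write_csv(report$aggregates, paths["aggregates"])
  readr::write_csv(report$rb, paths["rb"])
  grDevices::png(paths["plot"], width = 900, height = 600)
  print(autoplot(report))
  grDevices::dev.off()
  jsonlite::write_json(
    list(
      reference_id = report$reference_id,
      methods = report$methods,
      config = report$config[c(
        "bins", "tile", "include_reference", "seed", "extractor_seed"
      )],
      n_records = nrow(report$records),
      package_version = as.character(utils::packageVersion("stainbench"))
    ),
    paths["metadata"],
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(paths)
}
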