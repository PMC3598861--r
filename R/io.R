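read_tsv_tokens <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path)
  lines <- gsub("−", "-", lines)  # accept unicode minus on read
  lapply(strsplit(lines, "[\t ]+"), function(tok) {
    tok <- tok[nzchar(tok)]
    suppressWarnings(v <- as.numeric(tok))
    if (any(is.na(v) & toupper(tok) != "NAN"))
      stop("non-numeric token in ", path)
    v[toupper(tok) == "NAN"] <- NaN
    v
  })
}

#' Read a weight matrix from TSV
#'
#' Reads a square whitespace-delimited matrix in the printed-table layout
#' (N rows of N columns, `NaN` allowed, unicode minus accepted). The matrix
#' must be square; asymmetry beyond `1e-9` is an error, smaller asymmetry is
#' symmetrized with a warning.
#'
#' @param path File path.
#' @return Numeric N x N matrix.
#' @export
read_weight_matrix <- function(path) {
  rows <- read_tsv_tokens(path)
  nc <- unique(lengths(rows))
  if (length(nc) != 1) stop("ragged rows in ", path)
  W <- do.call(rbind, rows)
  if (nrow(W) != ncol(W)) stop("weight matrix must be square: ", path)
  asym <- max(abs(W - t(W)), na.rm = TRUE)
  if (asym > 1e-9) stop("weight matrix is not symmetric (max asymmetry ",
                        signif(asym, 3), ")")
  if (asym > 0) {
    warning("small asymmetry (", signif(asym, 3), ") symmetrized")
    W <- (W + t(W)) / 2
  }
  W
}

#' Write a weight matrix as TSV
#'
#' Two-decimal formatting mirroring the printed tables; `NA`/`NaN` entries are
#' written as the literal `NaN`, ASCII minus throughout.
#'
#' @param weights Numeric matrix.
#' @param path File path.
#' @param digits Decimal places (default 2).
#' @export
write_weight_matrix <- function(weights, path, digits = 2) {
  fm <- function(v) ifelse(is.na(v), "NaN", formatC(v, format = "f",
                                                    digits = digits))
  lines <- apply(weights, 1, function(r) paste(fm(r), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a threshold vector from TSV
#'
#' A single whitespace-delimited row; `NaN` marks the undefined threshold of a
#' degenerate unit and is returned as `NaN`.
#'
#' @param path File path.
#' @return Numeric vector.
#' @export
read_threshold_vector <- function(path) {
  rows <- read_tsv_tokens(path)
  if (length(rows) != 1) stop("threshold file must contain a single row: ", path)
  rows[[1]]
}

#' Write a threshold vector as TSV
#' @param thresholds Numeric vector (`NA`/`NaN` written as `NaN`).
#' @param path File path.
#' @param digits Decimal places (default 2).
#' @export
write_threshold_vector <- function(thresholds, path, digits = 2) {
  fm <- ifelse(is.na(thresholds), "NaN",
               formatC(thresholds, format = "f", digits = digits))
  writeLines(paste(fm, collapse = "\t"), path)
  invisible(path)
}

#' Read / write a binary raster as TSV
#'
#' Rasters are stored as 0/1 TSV with a unit header row (`MSb1..MSbN`), one
#' row per unit; unit flags travel in a JSON sidecar (`<path>.flags.json`).
#'
#' @param path File path.
#' @return For `read_raster`, a `binary_raster`.
#' @export
read_raster <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  M <- t(as.matrix(x))
  as_raster(M)
}

#' @rdname read_raster
#' @param raster A `binary_raster` or 0/1 matrix.
#' @export
write_raster <- function(raster, path) {
  raster <- as_raster(raster)
  M <- raster$values
  if (is.null(rownames(M))) rownames(M) <- paste0("MSb", seq_len(nrow(M)))
  utils::write.table(t(M), path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(stats::setNames(raster$flags, rownames(M))),
                       paste0(path, ".flags.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Serialize a DMN configuration to JSON
#'
#' @param net A `dmn_network`.
#' @param path File path.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "dmn_network"))
  payload <- list(
    n = net$n, seed = net$seed, delta = net$delta,
    flux_constants = net$flux_constants,
    stimuli = as.list(net$stimuli),
    flux_edges = net$flux_edges,
    signal_edges = net$signal_edges,
    flux_params = net$flux_params,
    init_state = net$init_state,
    knots = net$knots
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  comp <- c("amplitude", "baseline", "frequency")
  fp <- as.matrix(p$flux_params); colnames(fp) <- comp
  is <- as.matrix(p$init_state); colnames(is) <- comp
  net <- structure(list(
    flux_edges = as.data.frame(p$flux_edges),
    signal_edges = as.data.frame(p$signal_edges),
    flux_params = fp,
    init_state = is,
    n = as.integer(p$n), stimuli = unlist(p$stimuli), delta = p$delta,
    flux_constants = as.numeric(p$flux_constants),
    knots = lapply(p$knots, function(k) list(x = as.numeric(k$x),
                                             y = as.numeric(k$y))),
    seed = as.integer(p$seed)
  ), class = "dmn_network")
  validate_network(net)
}

fixture_captions <- list(
  T2 = list(mean = 0.59, sd = 39.04, min = -74.57, max = 81.05),
  T3 = list(mean = 0.37, sd = 2.83, min = -6.66, max = 18.31),
  T4 = list(mean = -1.26, sd = 4.29, min = -7.33, max = 6.16)
)

fixture_files <- c(T2 = "table2_thresholds.tsv",
                   T3 = "table3_weights.tsv",
                   T4 = "table4_thresholds.tsv")

#' Embedded coupling-table fixtures
#'
#' The published 18-unit coupling tables shipped with the package: `T3` is the
#' 18 x 18 learned weight matrix (two-stimulus condition), `T2` and `T4` the
#' threshold vectors of the one- and two-stimulus conditions; `T4` carries one
#' `NaN` at position 15, the degenerate always-off subsystem whose threshold
#' is formally infinite. Each fixture records the caption statistics printed
#' with its table.
#'
#' @param id One of `"T2"`, `"T3"`, `"T4"`.
#' @return A list of class `paper_fixture` with `id`, `payload` (matrix or
#'   vector) and `caption` (mean, sd, min, max).
#' @export
#' @examples
#' summarize_fixture(paper_fixture("T3"))
paper_fixture <- function(id = c("T3", "T2", "T4")) {
  id <- match.arg(id)
  path <- system.file("extdata", fixture_files[[id]], package = "attractornet",
                      mustWork = TRUE)
  payload <- if (id == "T3") read_weight_matrix(path)
             else read_threshold_vector(path)
  structure(list(id = id, payload = payload,
                 caption = fixture_captions[[id]]),
            class = "paper_fixture")
}

#' Summary statistics of a fixture payload
#'
#' Mean, standard deviation (sample, n-1), minimum and maximum over all
#' payload entries, `NaN` entries excluded (a degenerate unit's undefined
#' threshold does not enter the averages).
#'
#' @param fixture A `paper_fixture`, or any numeric matrix/vector.
#' @return Named list with `mean`, `sd`, `min`, `max`, `n`.
#' @export
summarize_fixture <- function(fixture) {
  v <- if (inherits(fixture, "paper_fixture")) fixture$payload else fixture
  v <- as.numeric(v)
  v <- v[!is.na(v)]
  list(mean = mean(v), sd = stats::sd(v), min = min(v), max = max(v),
       n = length(v))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages from network generation to attractor validation,
#' writing each stage's artifacts and a JSON manifest (inputs, outputs, seeds)
#' into `out_dir`. Stages are resumable: a stage whose upstream artifact is
#' missing from `out_dir` (and was not produced in this call) raises a
#' dependency error naming the absent file.
#'
#' @param seed Integer seed controlling every random stage.
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of `c("simulate", "binarize", "learn", "analyze",
#'   "memories", "hopfield")` in pipeline order; `"simulate"` includes network
#'   generation.
#' @param n Network size.
#' @param n_transitions Transition intervals to simulate.
#' @param burn_in Intervals discarded before analysis.
#' @param temperature Learning temperature.
#' @param stability_temperature Temperature of the attractor validation run.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(seed, out_dir,
                         stages = c("simulate", "binarize", "learn", "analyze",
                                    "memories", "hopfield"),
                         n = 18L, n_transitions = 2000L, burn_in = 1000L,
                         temperature = 1, stability_temperature = 0.7) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  need <- function(f, stage) {
    if (!file.exists(pth(f)))
      stop("stage '", stage, "' requires missing artifact: ", pth(f))
    pth(f)
  }
  manifest <- list(seed = as.integer(seed), stages = stages,
                   parameters = list(n = n, n_transitions = n_transitions,
                                     burn_in = burn_in,
                                     temperature = temperature,
                                     stability_temperature = stability_temperature),
                   outputs = character(0))
  add_out <- function(f) manifest$outputs <<- c(manifest$outputs, f)

  if ("simulate" %in% stages) {
    net <- generate_network(seed = seed, n = n)
    traj <- dmn_simulate(net, n_transitions)
    write_network(net, pth("network.json")); add_out("network.json")
    amp <- amplitude_series(traj)
    utils::write.table(t(amp), pth("amplitude.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add_out("amplitude.tsv")
    labels <- classify_states(traj, burn_in = burn_in)
    jsonlite::write_json(as.list(labels), pth("state_labels.json"),
                         auto_unbox = TRUE)
    add_out("state_labels.json")
  }
  if ("binarize" %in% stages) {
    ampf <- need("amplitude.tsv", "binarize")
    amp <- t(as.matrix(utils::read.table(ampf, header = TRUE, sep = "\t",
                                         check.names = FALSE)))
    raster <- binarize(amp)
    write_raster(raster, pth("raster.tsv")); add_out("raster.tsv")
  }
  if ("learn" %in% stages) {
    raster <- read_raster(need("raster.tsv", "learn"))
    fit <- boltzmann_fit(raster, method = "mflr", temperature = temperature,
                         burn_in = burn_in, ridge = 1e-8)
    write_weight_matrix(coef(fit, "weights"), pth("weights.tsv"))
    write_threshold_vector(coef(fit, "thresholds"), pth("thresholds.tsv"))
    add_out("weights.tsv"); add_out("thresholds.tsv")
    jsonlite::write_json(list(excluded = fit$excluded,
                              temperature = temperature),
                         pth("fit_meta.json"), auto_unbox = TRUE)
    add_out("fit_meta.json")
  }
  if ("analyze" %in% stages) {
    W <- read_weight_matrix(need("weights.tsv", "analyze"))
    th <- read_threshold_vector(need("thresholds.tsv", "analyze"))
    raster <- read_raster(need("raster.tsv", "analyze"))
    stats <- compute_moments(raster, burn_in = burn_in)
    model <- coupling_model(W, th, temperature)
    excl <- which(is.na(th) | stats$flags != "ok")
    report <- list(
      entropy_bits = entropy_mf(stats, excluded = excl),
      energy = energy_mf(model, stats, excluded = excl),
      weights = weight_distribution_summary(model)
    )
    jsonlite::write_json(report, pth("analysis.json"), auto_unbox = TRUE,
                         digits = NA)
    add_out("analysis.json")
  }
  if ("memories" %in% stages) {
    W <- read_weight_matrix(need("weights.tsv", "memories"))
    mem <- exhaustive_lse(W)
    utils::write.table(mem$patterns, pth("memories.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(list(cost = mem$cost, method = mem$method,
                              seed = as.integer(seed)),
                         pth("memories.json"), auto_unbox = TRUE, digits = NA)
    add_out("memories.tsv"); add_out("memories.json")
  }
  if ("hopfield" %in% stages) {
    W <- read_weight_matrix(need("weights.tsv", "hopfield"))
    th <- read_threshold_vector(need("thresholds.tsv", "hopfield"))
    mem <- as.matrix(utils::read.table(need("memories.tsv", "hopfield"),
                                       sep = "\t"))
    model <- coupling_model(W, th, stability_temperature)
    rep1 <- stability_test(model, mem[1, ],
                           temperature = stability_temperature, seed = seed)
    utils::write.table(
      data.frame(mcs = seq_along(rep1$distance), distance = rep1$distance),
      pth("stability_trace.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(verdict = rep1$verdict,
                              mean_distance = rep1$mean_distance,
                              temperature = stability_temperature),
                         pth("stability.json"), auto_unbox = TRUE, digits = NA)
    add_out("stability_trace.tsv"); add_out("stability.json")
  }
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}
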