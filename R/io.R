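#' Load a configuration file
#'
#' Reads a JSON configuration (flat key set as produced by [dump_config()]),
#' fills defaults and validates it; unknown keys are rejected with the
#' offending key named. A bare string is treated as a preset name.
#'
#' @param path Path to a JSON file.
#' @return A validated `seg_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.character(raw) && length(raw) == 1L) return(preset_config(raw))
  if (!is.list(raw)) stop("config file must contain a JSON object")
  if (!is.null(raw$clamps)) raw$clamps <- as.list(raw$clamps)
  validate_config(raw)
}

#' Write a configuration file
#'
#' Serializes a configuration to JSON at full numeric precision, such that
#' `load_config(dump_config(cfg, f))` reproduces `cfg` exactly.
#'
#' @param config A [seg_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  cfg <- validate_config(config)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Persist a run history
#'
#' Writes one wide TSV per recorded variable (rows = time, first column `t`,
#' then one column per cell; pre-birth entries are the literal string `NA`)
#' plus a `metadata.json` sidecar echoing the configuration, birth steps,
#' realized elongation rates and termination step. Values round-trip at full
#' precision. `format = "rds"` additionally stores the whole object as a
#' binary mirror for fast reloading.
#'
#' @param history A `seg_history`.
#' @param dir Output directory (created if needed).
#' @param format `"tsv"` (canonical) or `"rds"` (TSV plus binary mirror).
#' @return `dir`, invisibly.
#' @export
write_history <- function(history, dir, format = c("tsv", "rds")) {
  stopifnot(inherits(history, "seg_history"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (v in names(history$vars)) {
    m <- history$vars[[v]]
    # 17 significant digits guarantee binary64 round-trips exactly
    ch <- sprintf("%.17g", m)
    ch[is.na(m)] <- NA_character_
    dt <- data.table::as.data.table(matrix(ch, nrow(m)))
    data.table::setnames(dt, paste0("cell_", seq_len(ncol(m))))
    dt <- cbind(data.table::data.table(t = history$t), dt)
    data.table::fwrite(dt, file.path(dir, paste0(v, ".tsv")), sep = "\t",
                       na = "NA", quote = FALSE)
  }
  meta <- list(config = unclass(history$config), born = history$born,
               v_eff = history$v_eff,
               term_step = if (is.na(history$term_step)) NULL
                           else history$term_step,
               final_psc_active = history$final$psc_active,
               final_acc = history$final$acc)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  if (format == "rds") saveRDS(history, file.path(dir, "history.rds"))
  invisible(dir)
}

#' Reload a persisted run history
#'
#' @param dir Directory written by [write_history()].
#' @return A `seg_history` equivalent to the one written (metrics computed on
#'   it match the in-memory results exactly).
#' @export
read_history <- function(dir) {
  mf <- file.path(dir, "metadata.json")
  if (!file.exists(mf)) stop("not a history directory (no metadata.json): ", dir)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!is.null(meta$config$clamps)) meta$config$clamps <- as.list(meta$config$clamps)
  cfg <- validate_config(meta$config)
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  vars <- list()
  t <- NULL
  for (f in files) {
    v <- sub("\\.tsv$", "", basename(f))
    dt <- data.table::fread(f, sep = "\t", na.strings = "NA")
    t <- dt$t
    m <- as.matrix(dt[, -1L])
    dimnames(m) <- NULL
    storage.mode(m) <- "double"  # histories record everything as numeric
    vars[[v]] <- m
  }
  ord <- intersect(c("tau1", "phase", "osc", "tau2", "tau3", "switch",
                     "signal"), names(vars))
  vars <- vars[ord]
  h <- structure(list(vars = vars, config = cfg,
                      born = as.integer(meta$born),
                      t = as.integer(t), v_eff = as.numeric(meta$v_eff),
                      term_step = if (is.null(meta$term_step) ||
                                      is.na(meta$term_step)) NA_integer_
                                  else as.integer(meta$term_step)),
                 class = "seg_history")
  fin <- .row_state(h, length(t))
  fin$t <- t[length(t)]
  fin$born <- h$born
  fin$acc <- as.numeric(meta$final_acc)
  fin$psc_active <- isTRUE(meta$final_psc_active)
  h$final <- fin
  h
}

#' Render a kymograph
#'
#' Writes a PNG of one recorded variable with cell index on the horizontal
#' axis and time running down the vertical axis; cells not yet born are
#' blank. Optional overlays trace the determination front (red) and the
#' posterior tip (purple).
#'
#' @param history A `seg_history`.
#' @param variable Recorded variable name (e.g. `"osc"`, `"tau1"`,
#'   `"switch"`).
#' @param path Output PNG path.
#' @param overlays Draw front/tip overlays (default `TRUE`).
#' @param width,height Image size in pixels.
#' @return `path`, invisibly.
#' @export
render_kymograph <- function(history, variable, path, overlays = TRUE,
                             width = 640, height = 640) {
  stopifnot(inherits(history, "seg_history"))
  m <- history$vars[[variable]]
  if (is.null(m)) stop("unknown or unrecorded variable: ", variable)
  if (nrow(m) < 1L || ncol(m) < 1L || all(is.na(m)))
    stop("history is empty; nothing to render")
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  pal <- grDevices::hcl.colors(100, "viridis")
  graphics::image(x = seq_len(ncol(m)), y = history$t, z = t(m),
                  ylim = rev(range(history$t)), col = pal,
                  xlab = "cell index (anterior to posterior)",
                  ylab = "time (steps)",
                  main = paste0(variable, " - ", history$config$variant),
                  useRaster = TRUE)
  if (overlays) {
    curves <- summary_curves(history)
    graphics::lines(curves$wavefront - 0.5, curves$t, col = "red", lwd = 2)
    graphics::lines(curves$tip + 0.5, curves$t, col = "purple", lwd = 2)
  }
  invisible(path)
}
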