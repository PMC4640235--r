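# Serialization of datasets to/from the self-descriptive XML exchange
# format, plus configuration-template save/load and flat-array parity
# exports.  The element vocabulary is frozen in
# inst/extdata/exchange-schema.json; the validator rejects anything
# outside it.

fmt_num <- function(x) sprintf("%.17g", as.numeric(x))

schema_vocabulary <- function() {
  path <- system.file("extdata", "exchange-schema.json", package = "mrsxml")
  if (!nzchar(path)) {
    mrs_io_error("exchange-schema.json not found in the installed package")
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}

## ---- step (de)serialization -----------------------------------------

add_range_child <- function(node, name, r) {
  xml2::xml_add_child(node, name, upper = fmt_num(r$upper),
                      lower = fmt_num(r$lower))
}

parse_range_node <- function(node) {
  ppm_range(as.numeric(xml2::xml_attr(node, "upper")),
            as.numeric(xml2::xml_attr(node, "lower")))
}

add_step_node <- function(parent, rec) {
  p <- rec$parameters
  node <- switch(rec$step_id,
    SetReference = xml2::xml_add_child(parent, "SetReference",
                                       reference = fmt_num(p$reference)),
    Apodize = xml2::xml_add_child(parent, "Apodize", shape = p$shape,
                                  linewidth = fmt_num(p$linewidth)),
    WaterFiltering = {
      n <- xml2::xml_add_child(parent, "WaterFiltering",
                               lorentzians = as.character(p$n_lorentzians))
      for (r in p$regions) add_range_child(n, "Region", r)
      n
    },
    BaselineCorrection = {
      n <- xml2::xml_add_child(parent, "BaselineCorrection")
      for (r in p$regions) add_range_child(n, "Region", r)
      n
    },
    ChangePoints = {
      n <- xml2::xml_add_child(parent, "ChangePoints",
                               points = as.character(p$target_points))
      add_range_child(n, "Range", p$range)
      n
    },
    SetToZero = {
      n <- xml2::xml_add_child(parent, "SetToZero")
      for (r in p$intervals) add_range_child(n, "Region", r)
      n
    },
    Normalization = xml2::xml_add_child(parent, "Normalization",
                                        type = p$type %||% "l2"),
    AlignmentCorrection = {
      n <- xml2::xml_add_child(
        parent, "AlignmentCorrection",
        brainPreset = tolower(as.character(isTRUE(p$brain_1p5T_preset)))
      )
      for (pk in p$peaks) xml2::xml_add_child(n, "Peak", ppm = fmt_num(pk))
      add_range_child(n, "Noise", p$noise)
      n
    },
    OutputRange = {
      n <- xml2::xml_add_child(parent, "OutputRange")
      add_range_child(n, "Range", p$range)
      n
    },
    mrs_validation_error(sprintf("cannot serialize unknown step '%s'",
                                 rec$step_id))
  )
  invisible(node)
}

parse_step_node <- function(node) {
  name <- xml2::xml_name(node)
  children_ranges <- function(tag) {
    lapply(xml2::xml_find_all(node, tag), parse_range_node)
  }
  params <- switch(name,
    SetReference = list(reference = as.numeric(xml2::xml_attr(node, "reference"))),
    Apodize = list(shape = xml2::xml_attr(node, "shape"),
                   linewidth = as.numeric(xml2::xml_attr(node, "linewidth"))),
    WaterFiltering = list(
      n_lorentzians = as.integer(xml2::xml_attr(node, "lorentzians")),
      regions = children_ranges("Region")
    ),
    BaselineCorrection = list(regions = children_ranges("Region")),
    ChangePoints = list(
      target_points = as.integer(xml2::xml_attr(node, "points")),
      range = parse_range_node(xml2::xml_find_first(node, "Range"))
    ),
    SetToZero = list(intervals = children_ranges("Region")),
    Normalization = list(type = xml2::xml_attr(node, "type")),
    AlignmentCorrection = list(
      peaks = vapply(xml2::xml_find_all(node, "Peak"),
                     function(x) as.numeric(xml2::xml_attr(x, "ppm")),
                     numeric(1)),
      noise = parse_range_node(xml2::xml_find_first(node, "Noise")),
      brain_1p5T_preset = identical(xml2::xml_attr(node, "brainPreset"), "true")
    ),
    OutputRange = list(
      range = parse_range_node(xml2::xml_find_first(node, "Range"))
    ),
    mrs_validation_error(sprintf("unknown step element '%s'", name))
  )
  step_record(name, params)
}

## ---- voxel (de)serialization ----------------------------------------

fill_voxel_node <- function(node, vx) {
  sp <- vx$spectrum
  p <- sp$params
  n <- length(sp$intensities)
  xml2::xml_set_attr(node, "points", as.character(n))
  xml2::xml_set_attr(node, "storage", "complex")
  xml2::xml_set_attr(node, "ppmFirst", fmt_num(sp$axis[1]))
  xml2::xml_set_attr(node, "ppmStep", fmt_num(ppm_step(p)))
  xml2::xml_set_attr(node, "transmitterFrequency",
                     fmt_num(p$transmitter_frequency))
  xml2::xml_set_attr(node, "nucleus", p$nucleus)
  xml2::xml_add_child(node, "Label", vx$label)
  if (!is.null(vx$snr)) {
    xml2::xml_add_child(node, "SNR", value = fmt_num(vx$snr$snr),
                        maxPeak = fmt_num(vx$snr$max_peak),
                        noiseStd = fmt_num(vx$snr$noise_std))
  }
  data_txt <- paste(
    fmt_num(as.vector(rbind(Re(sp$intensities), Im(sp$intensities)))),
    collapse = " "
  )
  xml2::xml_add_child(node, "Data", data_txt)
  invisible(node)
}

parse_voxel_node <- function(node) {
  n <- as.integer(xml2::xml_attr(node, "points"))
  ppm_first <- as.numeric(xml2::xml_attr(node, "ppmFirst"))
  step <- as.numeric(xml2::xml_attr(node, "ppmStep"))
  f0 <- as.numeric(xml2::xml_attr(node, "transmitterFrequency"))
  nucleus <- xml2::xml_attr(node, "nucleus")
  storage <- xml2::xml_attr(node, "storage")
  params <- acquisition_params(
    transmitter_frequency = f0,
    sweep_width = step * f0 * n,
    num_points = n,
    reference_ppm = ppm_first - carrier_index0(n) * step,
    nucleus = if (is.na(nucleus)) "1H" else nucleus
  )
  vals <- as.numeric(strsplit(
    trimws(xml2::xml_text(xml2::xml_find_first(node, "Data"))), "\\s+"
  )[[1]])
  x <- if (identical(storage, "real")) {
    complex(real = vals, imaginary = 0)
  } else {
    complex(real = vals[c(TRUE, FALSE)], imaginary = vals[c(FALSE, TRUE)])
  }
  if (length(x) != n) {
    mrs_validation_error(sprintf(
      "Voxel Data holds %d values but the points attribute says %d",
      length(x), n
    ))
  }
  label_node <- xml2::xml_find_first(node, "Label")
  label <- if (inherits(label_node, "xml_missing")) "***" else xml2::xml_text(label_node)
  snr_node <- xml2::xml_find_first(node, "SNR")
  snr <- if (inherits(snr_node, "xml_missing")) NULL else {
    structure(
      list(snr = as.numeric(xml2::xml_attr(snr_node, "value")),
           max_peak = as.numeric(xml2::xml_attr(snr_node, "maxPeak")),
           noise_std = as.numeric(xml2::xml_attr(snr_node, "noiseStd"))),
      class = "mrs_snr"
    )
  }
  pos <- c(xml2::xml_attr(node, "Xaxis"), xml2::xml_attr(node, "Yaxis"),
           xml2::xml_attr(node, "Zaxis"))
  position <- if (all(!is.na(pos))) as.integer(pos) else NULL
  voxel_record(spectrum(x, params), label = label, snr = snr,
               position = position)
}

## ---- dataset export / import ----------------------------------------

#' Export a dataset to the XML exchange format
#'
#' Writes the root `DATASET` element with its `Preprocessing` child
#' (one element per applied step -- absence of an element means the
#' step was not performed -- plus the always-required
#' `AdditionalInformation` with `Name` and `Place`) and exactly one
#' payload: a `Voxel` element for single-voxel data or a `Grid` of
#' `Voxel` elements, each carrying `Xaxis`/`Yaxis`/`Zaxis` position
#' attributes with `Zaxis` fixed to 1.  The processing date is assigned
#' automatically at export.
#'
#' @param ds An [mrs_dataset()] object.
#' @param path Destination file path.
#' @return The path, invisibly.
#' @export
export_dataset <- function(ds, path) {
  if (!inherits(ds, "mrs_dataset")) {
    mrs_validation_error("'ds' must be an mrs_dataset object")
  }
  info <- ds$preprocessing$additional_info
  if (!nzchar(trimws(info$name)) || !nzchar(trimws(info$place))) {
    mrs_validation_error(
      "User's Name and Place are compulsory for export"
    )
  }
  doc <- xml2::xml_new_root("DATASET")
  pre <- xml2::xml_add_child(doc, "Preprocessing")
  ord <- vapply(ds$preprocessing$steps,
                function(s) STEP_ORDER[[s$step_id]], integer(1))
  for (rec in ds$preprocessing$steps[order(ord)]) add_step_node(pre, rec)
  ai <- xml2::xml_add_child(pre, "AdditionalInformation")
  xml2::xml_add_child(ai, "Name", info$name)
  xml2::xml_add_child(ai, "Place", info$place)
  xml2::xml_add_child(ai, "Date",
                      info$date %||% format(Sys.Date(), "%Y-%m-%d"))
  xml2::xml_add_child(ai, "Label", info$label)
  if (length(info$keywords)) {
    kw <- xml2::xml_add_child(ai, "Keywords")
    for (k in info$keywords) xml2::xml_add_child(kw, "Keyword", k)
  }
  if (nzchar(info$meta_data)) {
    xml2::xml_add_child(ai, "MetaData", info$meta_data)
  }
  if (ds$kind == "SV") {
    vx_node <- xml2::xml_add_child(doc, "Voxel")
    fill_voxel_node(vx_node, ds$payload)
  } else {
    g <- ds$payload
    g_node <- xml2::xml_add_child(doc, "Grid", rows = as.character(g$rows),
                                  cols = as.character(g$cols))
    for (vx in g$voxels) {
      vn <- xml2::xml_add_child(g_node, "Voxel")
      xml2::xml_set_attr(vn, "Xaxis", as.character(vx$position[1]))
      xml2::xml_set_attr(vn, "Yaxis", as.character(vx$position[2]))
      xml2::xml_set_attr(vn, "Zaxis", "1")
      fill_voxel_node(vn, vx)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a dataset from the XML exchange format
#'
#' Validates the document against the shipped schema vocabulary (any
#' violation raises a validation error naming the offending element)
#' and reconstructs the full dataset: provenance, metadata, labels,
#' SNR and the spectral payload.
#'
#' @param path Path to an exchange-format XML file.
#' @return An [mrs_dataset()] object.
#' @export
read_dataset <- function(path) {
  report <- validate_dataset(path)
  if (length(report)) {
    mrs_validation_error(paste0(
      "invalid exchange file: ", paste(report, collapse = "; ")
    ))
  }
  doc <- xml2::read_xml(path)
  pre <- xml2::xml_find_first(doc, "Preprocessing")
  step_nodes <- xml2::xml_children(pre)
  step_nodes <- step_nodes[xml2::xml_name(step_nodes) != "AdditionalInformation"]
  steps <- lapply(step_nodes, parse_step_node)
  ai <- xml2::xml_find_first(pre, "AdditionalInformation")
  get_txt <- function(tag, default = "") {
    nd <- xml2::xml_find_first(ai, tag)
    if (inherits(nd, "xml_missing")) default else xml2::xml_text(nd)
  }
  keywords <- vapply(xml2::xml_find_all(ai, "Keywords/Keyword"),
                     xml2::xml_text, character(1))
  meta_node <- xml2::xml_find_first(ai, "MetaData")
  info <- additional_info(
    name = get_txt("Name"),
    place = get_txt("Place"),
    label = get_txt("Label", "***"),
    keywords = keywords,
    meta_data = if (inherits(meta_node, "xml_missing")) "" else xml2::xml_text(meta_node),
    date = {
      d <- get_txt("Date", "")
      if (nzchar(d)) d else NULL
    }
  )
  vox_node <- xml2::xml_find_first(doc, "Voxel")
  if (!inherits(vox_node, "xml_missing")) {
    payload <- parse_voxel_node(vox_node)
  } else {
    g_node <- xml2::xml_find_first(doc, "Grid")
    rows <- as.integer(xml2::xml_attr(g_node, "rows"))
    cols <- as.integer(xml2::xml_attr(g_node, "cols"))
    vnodes <- xml2::xml_find_all(g_node, "Voxel")
    voxels <- vector("list", rows * cols)
    for (vn in vnodes) {
      vx <- parse_voxel_node(vn)
      i <- (vx$position[2] - 1L) * cols + vx$position[1]
      voxels[[i]] <- vx
    }
    payload <- grid_record(voxels, rows, cols)
  }
  mrs_dataset(preprocessing_record(steps, info), payload)
}

## ---- validator -------------------------------------------------------

check_voxel_node <- function(node, voc, where, report) {
  kids <- xml2::xml_children(node)
  unknown <- setdiff(xml2::xml_name(kids), voc$voxel_children)
  for (u in unknown) {
    report <- c(report, sprintf("%s: unknown element '%s'", where, u))
  }
  for (attr_name in c("points", "ppmFirst", "ppmStep", "transmitterFrequency")) {
    if (is.na(xml2::xml_attr(node, attr_name))) {
      report <- c(report, sprintf("%s: missing attribute '%s'", where, attr_name))
    }
  }
  extra <- setdiff(names(xml2::xml_attrs(node)), voc$voxel_attributes)
  for (a in extra) {
    report <- c(report, sprintf("%s: unknown attribute '%s'", where, a))
  }
  if (inherits(xml2::xml_find_first(node, "Data"), "xml_missing")) {
    report <- c(report, sprintf("%s: missing Data element", where))
  } else if (!is.na(xml2::xml_attr(node, "points"))) {
    n <- as.integer(xml2::xml_attr(node, "points"))
    vals <- strsplit(trimws(xml2::xml_text(
      xml2::xml_find_first(node, "Data")
    )), "\\s+")[[1]]
    expect <- if (identical(xml2::xml_attr(node, "storage"), "real")) n else 2L * n
    if (length(vals) != expect) {
      report <- c(report, sprintf(
        "%s: Data holds %d values, expected %d", where, length(vals), expect
      ))
    }
  }
  report
}

#' Validate an exchange-format XML file
#'
#' Checks the document against the shipped schema vocabulary: required
#' nodes (`AdditionalInformation` with non-empty `Name` and `Place` is
#' always required), exactly one payload, step-element ordering,
#' `Zaxis == 1` on every grid voxel, keyword length, and rejection of
#' any unknown element or attribute (the format is anonymizing by
#' construction: there is no sanctioned place for identifying
#' information).
#'
#' @param path Path to the XML file to check.
#' @return Character vector of violations; empty when the file is
#'   valid.
#' @export
validate_dataset <- function(path) {
  if (!file.exists(path)) {
    mrs_io_error(sprintf("file not found: %s", path))
  }
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    mrs_io_error(sprintf("cannot parse XML: %s", conditionMessage(e)))
  })
  voc <- schema_vocabulary()
  report <- character()
  if (xml2::xml_name(doc) != voc$root) {
    return(sprintf("root element is '%s', expected '%s'",
                   xml2::xml_name(doc), voc$root))
  }
  kids <- xml2::xml_children(doc)
  kid_names <- xml2::xml_name(kids)
  for (u in setdiff(kid_names, voc$dataset_children)) {
    report <- c(report, sprintf("DATASET: unknown element '%s'", u))
  }
  if (sum(kid_names == "Preprocessing") != 1) {
    report <- c(report, "DATASET must contain exactly one Preprocessing element")
  }
  n_payload <- sum(kid_names %in% c("Voxel", "Grid"))
  if (n_payload != 1) {
    report <- c(report, sprintf(
      "DATASET must contain exactly one payload (Voxel or Grid), found %d",
      n_payload
    ))
  }

  pre <- xml2::xml_find_first(doc, "Preprocessing")
  if (!inherits(pre, "xml_missing")) {
    pk <- xml2::xml_children(pre)
    pk_names <- xml2::xml_name(pk)
    for (u in setdiff(pk_names, voc$preprocessing_children)) {
      report <- c(report, sprintf("Preprocessing: unknown element '%s'", u))
    }
    step_ord <- STEP_ORDER[pk_names[pk_names %in% voc$steps]]
    if (length(step_ord) > 1 && any(diff(step_ord) < 0)) {
      report <- c(report, "Preprocessing: step elements out of pipeline order")
    }
    ai <- xml2::xml_find_first(pre, "AdditionalInformation")
    if (inherits(ai, "xml_missing")) {
      report <- c(report, "AdditionalInformation element is required")
    } else {
      for (tag in c("Name", "Place")) {
        nd <- xml2::xml_find_first(ai, tag)
        if (inherits(nd, "xml_missing") || !nzchar(trimws(xml2::xml_text(nd)))) {
          report <- c(report, sprintf(
            "AdditionalInformation: non-empty '%s' is compulsory", tag
          ))
        }
      }
      for (u in setdiff(xml2::xml_name(xml2::xml_children(ai)),
                        voc$additional_information_children)) {
        report <- c(report, sprintf(
          "AdditionalInformation: unknown element '%s'", u
        ))
      }
      kws <- xml2::xml_find_all(ai, "Keywords/Keyword")
      for (k in kws) {
        if (nchar(xml2::xml_text(k)) > voc$keyword_max_chars) {
          report <- c(report, sprintf(
            "keyword length exceeds %d characters: '%s'",
            voc$keyword_max_chars, xml2::xml_text(k)
          ))
        }
      }
    }
  }

  vox <- xml2::xml_find_first(doc, "Voxel")
  if (!inherits(vox, "xml_missing")) {
    report <- check_voxel_node(vox, voc, "Voxel", report)
  }
  g <- xml2::xml_find_first(doc, "Grid")
  if (!inherits(g, "xml_missing")) {
    rows <- suppressWarnings(as.integer(xml2::xml_attr(g, "rows")))
    cols <- suppressWarnings(as.integer(xml2::xml_attr(g, "cols")))
    if (is.na(rows) || is.na(cols)) {
      report <- c(report, "Grid: missing rows/cols attributes")
    }
    vnodes <- xml2::xml_find_all(g, "Voxel")
    if (!is.na(rows) && !is.na(cols) && length(vnodes) != rows * cols) {
      report <- c(report, sprintf(
        "Grid: %d Voxel elements, expected rows*cols = %d",
        length(vnodes), rows * cols
      ))
    }
    seen_topleft <- FALSE
    for (i in seq_along(vnodes)) {
      vn <- vnodes[[i]]
      where <- sprintf("Grid/Voxel[%d]", i)
      for (a in c("Xaxis", "Yaxis", "Zaxis")) {
        if (is.na(xml2::xml_attr(vn, a))) {
          report <- c(report, sprintf("%s: missing attribute '%s'", where, a))
        }
      }
      z <- xml2::xml_attr(vn, "Zaxis")
      if (!is.na(z) && z != as.character(voc$zaxis_fixed)) {
        report <- c(report, sprintf(
          "%s: Zaxis is '%s' but must be %s", where, z, voc$zaxis_fixed
        ))
      }
      if (identical(xml2::xml_attr(vn, "Xaxis"), "1") &&
          identical(xml2::xml_attr(vn, "Yaxis"), "1")) {
        seen_topleft <- TRUE
      }
      report <- check_voxel_node(vn, voc, where, report)
    }
    if (length(vnodes) > 0 && !seen_topleft) {
      report <- c(report, "Grid: no voxel at the top-left position [1, 1]")
    }
  }
  report
}

## ---- voxel labelling -------------------------------------------------

#' Assign a label to one voxel of a grid
#'
#' Addresses the voxel in matrix notation (top-left is `[1, 1]`); only
#' the addressed voxel's label changes, all others keep theirs (the
#' default being `"***"`).
#'
#' @param grid An [grid_record()] object.
#' @param row,col 1-based matrix indices.
#' @param label New label text.
#' @return The modified grid.
#' @export
set_voxel_label <- function(grid, row, col, label) {
  stopifnot(inherits(grid, "mrs_grid"))
  if (length(row) != 1 || length(col) != 1 ||
      row != round(row) || col != round(col) ||
      row < 1 || row > grid$rows || col < 1 || col > grid$cols) {
    mrs_parameter_error(sprintf(
      "voxel position [%s, %s] outside the %d x %d grid",
      row, col, grid$rows, grid$cols
    ))
  }
  i <- (as.integer(row) - 1L) * grid$cols + as.integer(col)
  grid$voxels[[i]]$label <- as.character(label)
  grid
}

## ---- configuration save/load ----------------------------------------

#' Save / load a pipeline configuration template
#'
#' Configurations round-trip losslessly:
#' `load_config(save_config(cfg, f))` equals `cfg`.
#'
#' @param cfg An `mrs_config` object.
#' @param path File path.
#' @return `save_config()` returns the path invisibly; `load_config()`
#'   returns the `mrs_config`.
#' @export
save_config <- function(cfg, path) {
  if (!is_config(cfg)) {
    mrs_parameter_error("'cfg' must be an mrs_config object")
  }
  doc <- xml2::xml_new_root("PipelineConfig")
  en <- function(x) tolower(as.character(isTRUE(x)))
  xml2::xml_add_child(doc, "SetReference", enabled = en(cfg$set_reference$enabled),
                      reference = fmt_num(cfg$set_reference$reference))
  xml2::xml_add_child(doc, "Apodize", enabled = en(cfg$apodize$enabled),
                      shape = cfg$apodize$shape,
                      linewidth = fmt_num(cfg$apodize$linewidth))
  wf <- xml2::xml_add_child(doc, "WaterFiltering",
                            enabled = en(cfg$water_filter$enabled),
                            lorentzians = as.character(cfg$water_filter$n_lorentzians))
  for (r in cfg$water_filter$regions) add_range_child(wf, "Region", r)
  bl <- xml2::xml_add_child(doc, "BaselineCorrection",
                            enabled = en(cfg$baseline$enabled))
  for (r in cfg$baseline$regions) add_range_child(bl, "Region", r)
  cp <- xml2::xml_add_child(doc, "ChangePoints",
                            enabled = en(cfg$change_points$enabled),
                            points = as.character(cfg$change_points$target_points))
  add_range_child(cp, "Range", cfg$change_points$range)
  sz <- xml2::xml_add_child(doc, "SetToZero",
                            enabled = en(cfg$set_to_zero$enabled))
  for (r in cfg$set_to_zero$intervals) add_range_child(sz, "Region", r)
  xml2::xml_add_child(doc, "Normalization",
                      enabled = en(cfg$normalization$enabled), type = "l2")
  al <- xml2::xml_add_child(doc, "AlignmentCorrection",
                            enabled = en(cfg$alignment$enabled),
                            brainPreset = en(cfg$alignment$brain_1p5T_preset))
  for (pk in cfg$alignment$peaks) {
    xml2::xml_add_child(al, "Peak", ppm = fmt_num(pk))
  }
  if (!is.null(cfg$alignment$noise)) {
    add_range_child(al, "Noise", cfg$alignment$noise)
  }
  orn <- xml2::xml_add_child(doc, "OutputRange",
                             enabled = en(cfg$output_range$enabled))
  add_range_child(orn, "Range", cfg$output_range$range)
  if (!is.null(cfg$snr_noise)) {
    sn <- xml2::xml_add_child(doc, "SnrNoise")
    add_range_child(sn, "Range", cfg$snr_noise)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    mrs_io_error(sprintf("configuration file not found: %s", path))
  }
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    mrs_io_error(sprintf("cannot parse XML: %s", conditionMessage(e)))
  })
  if (xml2::xml_name(doc) != "PipelineConfig") {
    mrs_validation_error(sprintf(
      "root element is '%s', expected 'PipelineConfig'", xml2::xml_name(doc)
    ))
  }
  known <- c("SetReference", "Apodize", "WaterFiltering", "BaselineCorrection",
             "ChangePoints", "SetToZero", "Normalization",
             "AlignmentCorrection", "OutputRange", "SnrNoise")
  kids <- xml2::xml_name(xml2::xml_children(doc))
  unknown <- setdiff(kids, known)
  if (length(unknown)) {
    mrs_validation_error(sprintf(
      "unknown step element '%s' in configuration", unknown[1]
    ))
  }
  nd <- function(tag) xml2::xml_find_first(doc, tag)
  enabled <- function(node) identical(xml2::xml_attr(node, "enabled"), "true")
  ranges_of <- function(node, tag) {
    lapply(xml2::xml_find_all(node, tag), parse_range_node)
  }
  cfg <- config_template()
  x <- nd("SetReference")
  cfg$set_reference <- list(enabled = enabled(x),
                            reference = as.numeric(xml2::xml_attr(x, "reference")))
  x <- nd("Apodize")
  cfg$apodize <- list(enabled = enabled(x),
                      shape = xml2::xml_attr(x, "shape"),
                      linewidth = as.numeric(xml2::xml_attr(x, "linewidth")))
  x <- nd("WaterFiltering")
  cfg$water_filter <- list(enabled = enabled(x),
                           n_lorentzians = as.integer(xml2::xml_attr(x, "lorentzians")),
                           regions = ranges_of(x, "Region"))
  x <- nd("BaselineCorrection")
  cfg$baseline <- list(enabled = enabled(x), regions = ranges_of(x, "Region"))
  x <- nd("ChangePoints")
  cfg$change_points <- list(enabled = enabled(x),
                            target_points = as.integer(xml2::xml_attr(x, "points")),
                            range = parse_range_node(xml2::xml_find_first(x, "Range")))
  x <- nd("SetToZero")
  cfg$set_to_zero <- list(enabled = enabled(x), intervals = ranges_of(x, "Region"))
  x <- nd("Normalization")
  cfg$normalization <- list(enabled = enabled(x))
  x <- nd("AlignmentCorrection")
  noise_node <- xml2::xml_find_first(x, "Noise")
  cfg$alignment <- list(
    enabled = enabled(x),
    peaks = vapply(xml2::xml_find_all(x, "Peak"),
                   function(p) as.numeric(xml2::xml_attr(p, "ppm")), numeric(1)),
    noise = if (inherits(noise_node, "xml_missing")) NULL else parse_range_node(noise_node),
    brain_1p5T_preset = identical(xml2::xml_attr(x, "brainPreset"), "true")
  )
  x <- nd("OutputRange")
  cfg$output_range <- list(enabled = enabled(x),
                           range = parse_range_node(xml2::xml_find_first(x, "Range")))
  x <- nd("SnrNoise")
  cfg["snr_noise"] <- list(if (inherits(x, "xml_missing")) NULL else {
    parse_range_node(xml2::xml_find_first(x, "Range"))
  })
  cfg
}

## ---- flat parity exports ---------------------------------------------

#' Flat matrix view of a dataset's spectra
#'
#' Mirrors the reader-script convention: single-voxel data becomes one
#' row, a grid becomes `rows * cols` rows in row-major voxel order,
#' all of equal length.
#'
#' @param ds An [mrs_dataset()] object.
#' @param part `"real"`, `"imaginary"` or `"complex"`.
#' @return A numeric (or complex) matrix, one voxel per row.
#' @export
spectra_matrix <- function(ds, part = c("real", "imaginary", "complex")) {
  stopifnot(inherits(ds, "mrs_dataset"))
  part <- match.arg(part)
  voxels <- if (ds$kind == "SV") list(ds$payload) else ds$payload$voxels
  m <- do.call(rbind, lapply(voxels, function(v) v$spectrum$intensities))
  switch(part, real = Re(m), imaginary = Im(m), complex = m)
}

#' Write a spectrum in the canonical flat ASCII layout
#'
#' One line of space-separated real intensities, highest ppm first
#' (for the canonical 512-point format the first value is the
#' intensity at 7.1 ppm).  Grid datasets produce one line per voxel in
#' row-major order.
#'
#' @param ds An [mrs_dataset()] object.
#' @param path Destination file path.
#' @return The path, invisibly.
#' @export
write_interpret <- function(ds, path) {
  m <- spectra_matrix(ds, "real")
  lines <- apply(m, 1, function(row) paste(fmt_num(row), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}
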