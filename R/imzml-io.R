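## imzML 1.1 reader/writer (continuous and processed modes, uncompressed or
## zlib-compressed binary arrays). m/z values are stored as 64-bit floats --
## ppm-scale windows need double precision -- and intensities as 32-bit
## floats, matching common converter output.

#' Pixel width from stage kinematics
#'
#' In a DESI-MSI raster one full MS scan corresponds to one pixel, so the
#' pixel width along the scan direction equals the lateral stage speed
#' multiplied by the scan cycle time.
#'
#' @param stageSpeed lateral stage speed, micrometres per second
#' @param cycleTime scan cycle time, seconds
#' @return pixel width in micrometres
#' @examples
#' pixelWidthFromKinematics(120.37, 114.6 / 120.37)  # 114.6 um
#' pixelWidthFromKinematics(53.69, 72.6 / 53.69)     # 72.6 um
#' @export
pixelWidthFromKinematics <- function(stageSpeed, cycleTime) {
    if (!is.numeric(stageSpeed) || !is.numeric(cycleTime) ||
        any(!is.finite(stageSpeed)) || any(!is.finite(cycleTime)) ||
        any(stageSpeed <= 0) || any(cycleTime <= 0))
        stop("stageSpeed and cycleTime must be positive finite numbers")
    stageSpeed * cycleTime
}

.ibd_path <- function(imzml_path) {
    sub("\\.imzML$", ".ibd", imzml_path, ignore.case = TRUE)
}

.format_uuid <- function(bytes) {
    # RFC 4122 version-4 layout from 16 raw bytes
    bytes[7] <- as.raw(bitwOr(bitwAnd(as.integer(bytes[7]), 0x0F), 0x40))
    bytes[9] <- as.raw(bitwOr(bitwAnd(as.integer(bytes[9]), 0x3F), 0x80))
    h <- paste(sprintf("%02x", as.integer(bytes)), collapse = "")
    list(text = sprintf("%s-%s-%s-%s-%s", substr(h, 1, 8), substr(h, 9, 12),
                        substr(h, 13, 16), substr(h, 17, 20),
                        substr(h, 21, 32)),
         bytes = bytes)
}

.num <- function(x) {
    # full-precision, non-scientific numeric formatting for XML attributes
    sub("\\.?0+$", "", sprintf("%.10f", x))
}

#' Write an MSIDataset as an imzML + ibd pair
#'
#' Writes a standard-conformant imzML 1.1 file with its binary ibd
#' companion. In continuous mode every pixel must share one m/z axis, which
#' is stored once; processed mode stores per-pixel axes. m/z arrays are
#' 64-bit floats, intensity arrays 32-bit floats, uncompressed.
#'
#' @param dataset an [MSIDataset-class]
#' @param path output path ending in `.imzML`; the ibd is written alongside
#' @param mode `"processed"` (default) or `"continuous"`
#' @return `path`, invisibly
#' @seealso [readImzML()]
#' @export
writeImzML <- function(dataset, path, mode = c("processed", "continuous")) {
    mode <- match.arg(mode)
    stopifnot(is(dataset, "MSIDataset"))
    validObject(dataset)
    nr <- dataset@nRows; nc <- dataset@nCols
    spectra <- dataset@spectra

    if (mode == "continuous") {
        ax <- spectra[[1L]]$mz
        same <- vapply(spectra, function(s)
            length(s$mz) == length(ax) && all(s$mz == ax), TRUE)
        if (!all(same))
            stop("continuous mode requires a shared m/z axis across all ",
                 "pixels; pixels differ (use mode = 'processed')")
    }

    ibd_path <- .ibd_path(path)
    uuid <- .format_uuid(as.raw(sample.int(256L, 16L, replace = TRUE) - 1L))

    con <- file(ibd_path, "wb")
    on.exit(close(con), add = TRUE)
    writeBin(uuid$bytes, con)
    offset <- 16

    n <- length(spectra)
    mz_off <- numeric(n); mz_len <- integer(n)
    int_off <- numeric(n); int_len <- integer(n)

    if (mode == "continuous") {
        ax <- spectra[[1L]]$mz
        writeBin(as.numeric(ax), con, size = 8, endian = "little")
        mz_off[] <- offset; mz_len[] <- length(ax)
        offset <- offset + 8 * length(ax)
        for (i in seq_len(n)) {
            v <- spectra[[i]]$intensity
            writeBin(as.numeric(v), con, size = 4, endian = "little")
            int_off[i] <- offset; int_len[i] <- length(v)
            offset <- offset + 4 * length(v)
        }
    } else {
        for (i in seq_len(n)) {
            s <- spectra[[i]]
            writeBin(as.numeric(s$mz), con, size = 8, endian = "little")
            mz_off[i] <- offset; mz_len[i] <- length(s$mz)
            offset <- offset + 8 * length(s$mz)
            writeBin(as.numeric(s$intensity), con, size = 4, endian = "little")
            int_off[i] <- offset; int_len[i] <- length(s$intensity)
            offset <- offset + 4 * length(s$intensity)
        }
    }

    geom <- dataset@geometry
    mode_acc <- if (mode == "continuous") "IMS:1000030" else "IMS:1000031"
    tic <- vapply(spectra, function(s) sum(s$intensity), 0)
    xs <- rep(seq_len(nc), times = nr)           # position x = col + 1
    ys <- rep(seq_len(nr), each = nc)            # position y = row + 1

    spec_xml <- sprintf(paste0(
        '      <spectrum defaultArrayLength="0" id="spectrum=%d" index="%d">\n',
        '        <referenceableParamGroupRef ref="spectrum1"/>\n',
        '        <cvParam cvRef="MS" accession="MS:1000285" name="total ion current" value="%s"/>\n',
        '        <scanList count="1">\n',
        '          <cvParam accession="MS:1000795" cvRef="MS" name="no combination"/>\n',
        '          <scan>\n',
        '            <referenceableParamGroupRef ref="scan1"/>\n',
        '            <cvParam accession="IMS:1000050" cvRef="IMS" name="position x" value="%d"/>\n',
        '            <cvParam accession="IMS:1000051" cvRef="IMS" name="position y" value="%d"/>\n',
        '          </scan>\n',
        '        </scanList>\n',
        '        <binaryDataArrayList count="2">\n',
        '          <binaryDataArray encodedLength="0">\n',
        '            <referenceableParamGroupRef ref="mzArray"/>\n',
        '            <cvParam accession="IMS:1000103" cvRef="IMS" name="external array length" value="%d"/>\n',
        '            <cvParam accession="IMS:1000104" cvRef="IMS" name="external encoded length" value="%.0f"/>\n',
        '            <cvParam accession="IMS:1000102" cvRef="IMS" name="external offset" value="%.0f"/>\n',
        '            <binary/>\n',
        '          </binaryDataArray>\n',
        '          <binaryDataArray encodedLength="0">\n',
        '            <referenceableParamGroupRef ref="intensityArray"/>\n',
        '            <cvParam accession="IMS:1000103" cvRef="IMS" name="external array length" value="%d"/>\n',
        '            <cvParam accession="IMS:1000104" cvRef="IMS" name="external encoded length" value="%.0f"/>\n',
        '            <cvParam accession="IMS:1000102" cvRef="IMS" name="external offset" value="%.0f"/>\n',
        '            <binary/>\n',
        '          </binaryDataArray>\n',
        '        </binaryDataArrayList>\n',
        '      </spectrum>'),
        seq_len(n), seq_len(n), .num(tic), xs, ys,
        mz_len, 8 * mz_len, mz_off,
        int_len, 4 * int_len, int_off)

    polarity <- dataset@metadata["polarity"]
    pol_xml <- if (!is.na(polarity) && identical(unname(polarity), "negative"))
        '      <cvParam cvRef="MS" accession="MS:1000129" name="negative scan" value=""/>\n'
    else if (!is.na(polarity) && identical(unname(polarity), "positive"))
        '      <cvParam cvRef="MS" accession="MS:1000130" name="positive scan" value=""/>\n'
    else ""

    header <- sprintf(paste0(
'<?xml version="1.0" encoding="ISO-8859-1"?>\n',
'<mzML xmlns="http://psi.hupo.org/ms/mzml" xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance" xsi:schemaLocation="http://psi.hupo.org/ms/mzml http://psidev.info/files/ms/mzML/xsd/mzML1.1.0_idx.xsd" version="1.1">\n',
'  <cvList count="3">\n',
'    <cv uri="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" id="MS" version="4.1.12"/>\n',
'    <cv uri="http://obo.cvs.sourceforge.net/*checkout*/obo/obo/ontology/phenotype/unit.obo" fullName="Unit Ontology" id="UO" version="12:10:2011"/>\n',
'    <cv uri="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo" fullName="Imaging MS Ontology" id="IMS" version="1.1.0"/>\n',
'  </cvList>\n',
'  <fileDescription>\n',
'    <fileContent>\n',
'      <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>\n',
'      <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>\n',
'      <cvParam cvRef="IMS" accession="%s" name="%s" value=""/>\n',
'      <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>\n',
'    </fileContent>\n',
'  </fileDescription>\n',
'  <referenceableParamGroupList count="4">\n',
'    <referenceableParamGroup id="mzArray">\n',
'      <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
'      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>\n',
'      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
'      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
'    </referenceableParamGroup>\n',
'    <referenceableParamGroup id="intensityArray">\n',
'      <cvParam cvRef="MS" accession="MS:1000521" name="32-bit float" value=""/>\n',
'      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>\n',
'      <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
'      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
'    </referenceableParamGroup>\n',
'    <referenceableParamGroup id="scan1">\n',
'      <cvParam cvRef="MS" accession="MS:1000093" name="increasing m/z scan"/>\n',
'    </referenceableParamGroup>\n',
'    <referenceableParamGroup id="spectrum1">\n',
'      <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>\n',
'      <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>\n',
'      <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>\n',
'%s',
'    </referenceableParamGroup>\n',
'  </referenceableParamGroupList>\n',
'  <softwareList count="1">\n',
'    <software id="rootMSI" version="%s">\n',
'      <cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="rootMSI"/>\n',
'    </software>\n',
'  </softwareList>\n',
'  <scanSettingsList count="1">\n',
'    <scanSettings id="scanSettings1">\n',
'      <cvParam cvRef="IMS" accession="IMS:1000401" name="top down"/>\n',
'      <cvParam cvRef="IMS" accession="IMS:1000413" name="flyback"/>\n',
'      <cvParam cvRef="IMS" accession="IMS:1000480" name="horizontal line scan"/>\n',
'      <cvParam cvRef="IMS" accession="IMS:1000491" name="linescan left right"/>\n',
'      <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>\n',
'      <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>\n',
'      <cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size (x)" value="%s" unitCvRef="UO" unitAccession="UO:0000017" unitName="micrometer"/>\n',
'      <cvParam cvRef="IMS" accession="IMS:1000047" name="pixel size y" value="%s" unitCvRef="UO" unitAccession="UO:0000017" unitName="micrometer"/>\n',
'    </scanSettings>\n',
'  </scanSettingsList>\n',
'  <instrumentConfigurationList count="1">\n',
'    <instrumentConfiguration id="IC1">\n',
'    </instrumentConfiguration>\n',
'  </instrumentConfigurationList>\n',
'  <dataProcessingList count="1">\n',
'    <dataProcessing id="export_from_rootMSI">\n',
'      <processingMethod order="0" softwareRef="rootMSI">\n',
'        <cvParam cvRef="MS" accession="MS:1000530" name="file format conversion" value="Output to imzML"/>\n',
'      </processingMethod>\n',
'    </dataProcessing>\n',
'  </dataProcessingList>\n',
'  <run defaultInstrumentConfigurationRef="IC1" id="run1">\n',
'    <spectrumList count="%d" defaultDataProcessingRef="export_from_rootMSI">\n'),
        mode_acc, mode, uuid$text, pol_xml,
        as.character(utils::packageVersion("rootMSI")),
        nc, nr, .num(geom@pixelWidth), .num(geom@pixelHeight), n)

    footer <- "\n    </spectrumList>\n  </run>\n</mzML>\n"

    out <- file(path, "wb")
    writeLines(c(header, paste(spec_xml, collapse = "\n"), footer), out,
               sep = "")
    close(out)
    invisible(path)
}

.decode_array <- function(raw_bytes, what, compression) {
    if (identical(compression, "zlib"))
        raw_bytes <- memDecompress(raw_bytes, type = "gzip")
    if (what == "double")
        readBin(raw_bytes, "double", n = length(raw_bytes) %/% 8L, size = 8,
                endian = "little")
    else
        readBin(raw_bytes, "double", n = length(raw_bytes) %/% 4L, size = 4,
                endian = "little")
}

.param_group_info <- function(doc) {
    groups <- xml2::xml_find_all(doc,
        "//*[local-name()='referenceableParamGroup']")
    info <- list()
    for (g in groups) {
        id <- xml2::xml_attr(g, "id")
        acc <- xml2::xml_attr(
            xml2::xml_find_all(g, ".//*[local-name()='cvParam']"),
            "accession")
        info[[id]] <- list(
            is_mz  = "MS:1000514" %in% acc,
            is_int = "MS:1000515" %in% acc,
            bits64 = "MS:1000523" %in% acc,
            zlib   = "MS:1000574" %in% acc)
    }
    info
}

#' Read an imzML + ibd pair into an MSIDataset
#'
#' Supports continuous and processed binary modes, 32/64-bit floats and
#' no/zlib compression. imzML 1-based pixel positions (x, y) are mapped to
#' 0-based `(row = y - 1, col = x - 1)` indices; the coordinate set must
#' tile a full rectangle. Pixel geometry is taken from the file's
#' `pixel size x`/`pixel size y` scan settings when present, otherwise from
#' `geometry`.
#'
#' @param path path to the `.imzML` file (the `.ibd` must sit alongside)
#' @param geometry optional [RasterGeometry-class] override used when the
#'   file carries no pixel-size metadata
#' @return an [MSIDataset-class]
#' @seealso [writeImzML()]
#' @export
readImzML <- function(path, geometry = NULL) {
    if (!file.exists(path)) stop("imzML file not found: ", path)
    ibd_path <- .ibd_path(path)
    if (!file.exists(ibd_path))
        stop("missing binary file: expected '", ibd_path,
             "' alongside '", path, "'")

    doc <- xml2::read_xml(path)
    pg <- .param_group_info(doc)

    grab <- function(acc) xml2::xml_attr(xml2::xml_find_all(doc, sprintf(
        "//*[local-name()='cvParam'][@accession='%s']", acc)), "value")

    fc_acc <- xml2::xml_attr(xml2::xml_find_all(doc, paste0(
        "//*[local-name()='fileContent']/*[local-name()='cvParam']")),
        "accession")
    continuous <- "IMS:1000030" %in% fc_acc

    xs <- as.integer(grab("IMS:1000050"))
    ys <- as.integer(grab("IMS:1000051"))
    n <- length(xs)
    if (n == 0L) stop("no spectra found in ", path)

    # external offsets/lengths come in document order, one pair (mz array
    # first or second) per spectrum; identify ordering from the first
    # spectrum's referenceableParamGroupRef (writer convention: constant
    # ordering across spectra)
    refs <- xml2::xml_attr(xml2::xml_find_all(doc, paste0(
        "//*[local-name()='binaryDataArray']/",
        "*[local-name()='referenceableParamGroupRef']")), "ref")
    offs <- as.numeric(grab("IMS:1000102"))
    lens <- as.integer(grab("IMS:1000103"))
    if (length(offs) != 2L * n || length(lens) != 2L * n)
        stop("malformed imzML: expected 2 external arrays per spectrum")
    first_is_mz <- if (length(refs) >= 1L && !is.null(pg[[refs[1L]]]))
        pg[[refs[1L]]]$is_mz else TRUE
    mz_idx <- seq(if (first_is_mz) 1L else 2L, by = 2L, length.out = n)
    int_idx <- seq(if (first_is_mz) 2L else 1L, by = 2L, length.out = n)

    mzgrp <- Filter(function(g) g$is_mz, pg)
    intgrp <- Filter(function(g) g$is_int, pg)
    mz_what <- if (length(mzgrp) && !mzgrp[[1L]]$bits64) "float" else "double"
    int_what <- if (length(intgrp) && intgrp[[1L]]$bits64) "double" else "float"
    mz_comp <- if (length(mzgrp) && mzgrp[[1L]]$zlib) "zlib" else "none"
    int_comp <- if (length(intgrp) && intgrp[[1L]]$zlib) "zlib" else "none"

    # raster extent and rectangularity
    nc <- max(xs); nr <- max(ys)
    key <- (ys - 1L) * nc + (xs - 1L)
    if (anyDuplicated(key))
        stop("duplicate pixel coordinates in ", path)
    missing_key <- setdiff(0:(nr * nc - 1L), key)
    if (length(missing_key)) {
        mx <- missing_key %% nc + 1L; my <- missing_key %/% nc + 1L
        stop("non-rectangular imzML raster; missing coordinate",
             if (length(missing_key) > 1L) "s" else "", " ",
             paste(sprintf("(%d,%d)", mx, my)[seq_len(min(10L,
                 length(missing_key)))], collapse = ", "),
             if (length(missing_key) > 10L) ", ..." else "")
    }

    con <- file(ibd_path, "rb")
    on.exit(close(con), add = TRUE)

    read_at <- function(offset, count, what, comp) {
        seek(con, where = offset, origin = "start")
        width <- if (what == "double") 8L else 4L
        .decode_array(readBin(con, "raw", n = count * width), what, comp)
    }

    nbytes_mz <- if (mz_what == "double") 8L else 4L
    nbytes_int <- if (int_what == "double") 8L else 4L

    spectra <- vector("list", n)
    shared_mz <- NULL
    for (i in seq_len(n)) {
        if (continuous && !is.null(shared_mz) &&
            offs[mz_idx[i]] == offs[mz_idx[1L]]) {
            mz <- shared_mz
        } else {
            mz <- read_at(offs[mz_idx[i]], lens[mz_idx[i]], mz_what, mz_comp)
            if (continuous && is.null(shared_mz)) shared_mz <- mz
        }
        inten <- read_at(offs[int_idx[i]], lens[int_idx[i]], int_what,
                         int_comp)
        if (length(mz) > 1L && any(diff(mz) <= 0))
            stop(sprintf("unsorted m/z array at pixel (x=%d, y=%d)",
                         xs[i], ys[i]))
        spectra[[i]] <- list(mz = mz, intensity = inten)
    }

    # reorder document-order spectra into row-major (row, col)
    ord <- order(key)
    spectra <- spectra[ord]

    px <- suppressWarnings(as.numeric(grab("IMS:1000046")))
    py <- suppressWarnings(as.numeric(grab("IMS:1000047")))
    if (length(px) == 1L && is.finite(px) && length(py) == 1L &&
        is.finite(py)) {
        allmz <- unlist(lapply(spectra, `[[`, "mz"), use.names = FALSE)
        rng <- if (length(allmz)) range(allmz) else c(50, 1000)
        geom <- rasterGeometry(pixelWidth = px, pixelHeight = py,
                               mzRange = c(min(rng[1], 50),
                                           max(rng[2], 1000)))
    } else if (!is.null(geometry)) {
        geom <- geometry
    } else {
        stop("no pixel-size metadata in ", path,
             " and no geometry override supplied")
    }

    new("MSIDataset", spectra = spectra, nRows = nr, nCols = nc,
        geometry = geom,
        metadata = c(source = path,
                     mode = if (continuous) "continuous" else "processed"))
}
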