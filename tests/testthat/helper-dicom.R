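# DICOM fixtures are generated at test time with pydicom (the reference
# implementation), which also serves as the independent oracle for the
# package's reader.

has_pydicom <- function() {
  nzchar(Sys.which("python")) &&
    system2("python", c("-c", "import pydicom"), stdout = FALSE,
            stderr = FALSE) == 0
}

# frames: H x W x T integer array in 0..255 (grayscale), or
# H x W x T x 3 for RGB. Returns the DICOM path.
write_dicom_fixture <- function(frames, path,
                                photometric = "MONOCHROME2",
                                frame_time = NULL,
                                transfer = "explicit") {
  d <- dim(frames)
  rgb <- length(d) == 4
  H <- d[1]; W <- d[2]; Tn <- d[3]
  raw_path <- tempfile(fileext = ".bin")
  if (!rgb) {
    v <- unlist(lapply(seq_len(Tn), function(t)
      as.vector(t(frames[, , t]))))
  } else {
    # frame-major, row-major, interleaved samples
    v <- unlist(lapply(seq_len(Tn), function(t) {
      m <- sapply(1:3, function(ch) as.vector(t(frames[, , t, ch])))
      as.vector(t(m))
    }))
  }
  writeBin(as.raw(v), raw_path)
  py <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "import numpy as np",
    "import pydicom",
    "from pydicom.dataset import Dataset, FileMetaDataset",
    "from pydicom.uid import ExplicitVRLittleEndian, ImplicitVRLittleEndian, generate_uid",
    "raw, out, H, W, T, photometric, ftime, transfer, rgb = sys.argv[1:10]",
    "H, W, T = int(H), int(W), int(T)",
    "data = np.fromfile(raw, dtype=np.uint8)",
    "meta = FileMetaDataset()",
    "meta.MediaStorageSOPClassUID = pydicom.uid.UID('1.2.840.10008.5.1.4.1.1.3.1')",
    "meta.MediaStorageSOPInstanceUID = generate_uid()",
    "meta.TransferSyntaxUID = ExplicitVRLittleEndian if transfer == 'explicit' else ImplicitVRLittleEndian",
    "ds = Dataset()",
    "ds.file_meta = meta",
    "ds.SOPClassUID = meta.MediaStorageSOPClassUID",
    "ds.SOPInstanceUID = meta.MediaStorageSOPInstanceUID",
    "ds.Rows, ds.Columns = H, W",
    "ds.NumberOfFrames = T",
    "ds.SamplesPerPixel = 3 if rgb == '1' else 1",
    "if rgb == '1': ds.PlanarConfiguration = 0",
    "ds.PhotometricInterpretation = photometric",
    "ds.BitsAllocated = 8",
    "ds.BitsStored = 8",
    "ds.HighBit = 7",
    "ds.PixelRepresentation = 0",
    "if ftime != 'none': ds.FrameTime = ftime",
    "ds.PixelData = data.tobytes()",
    "ds.save_as(out, enforce_file_format=True)"
  ), py)
  status <- system2("python", c(py, raw_path, path, H, W, Tn, photometric,
                                if (is.null(frame_time)) "none" else frame_time,
                                transfer, if (rgb) "1" else "0"),
                    stdout = FALSE, stderr = "")
  if (status != 0) stop("pydicom fixture writer failed")
  path
}
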