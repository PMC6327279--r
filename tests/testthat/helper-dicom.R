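# Writes small DICOM fixtures with pydicom (an independent implementation of
# the format). Pixel values follow a deterministic formula recomputable in R,
# so no binary data is exchanged.

test_dicom_value <- function(frame, row, col) (7 * frame + 13 * row + 29 * col) %% 251

write_test_dicom <- function(path, n_frames = 3L, rows = 24L, cols = 24L,
                             rgb = FALSE, spacing = NULL) {
  script <- sprintf('
import numpy as np, pydicom
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian
nf, nr, nc = %d, %d, %d
f = np.arange(nf)[:, None, None]
r = np.arange(nr)[None, :, None]
c = np.arange(nc)[None, None, :]
base = ((7 * f + 13 * r + 29 * c) %% 251).astype(np.uint8)
meta = FileMetaDataset()
meta.MediaStorageSOPClassUID = pydicom.uid.SecondaryCaptureImageStorage
meta.MediaStorageSOPInstanceUID = pydicom.uid.generate_uid()
meta.TransferSyntaxUID = ExplicitVRLittleEndian
ds = Dataset(); ds.file_meta = meta
ds.Rows, ds.Columns = nr, nc
ds.NumberOfFrames = nf
ds.BitsAllocated = 8; ds.BitsStored = 8; ds.HighBit = 7
ds.PixelRepresentation = 0
rgb = %s
if rgb:
    ds.SamplesPerPixel = 3
    ds.PhotometricInterpretation = "RGB"
    ds.PlanarConfiguration = 0
    px = np.repeat(base[..., None], 3, axis=-1)   # achromatic RGB
else:
    ds.SamplesPerPixel = 1
    ds.PhotometricInterpretation = "MONOCHROME2"
    px = base
%s
ds.PixelData = px.tobytes()
ds.save_as(r"%s", enforce_file_format=True)
', n_frames, rows, cols, if (rgb) "True" else "False",
    if (is.null(spacing)) "" else
      sprintf('ds.PixelSpacing = ["%s", "%s"]', spacing, spacing),
    path)
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", sf, stdout = FALSE, stderr = FALSE)
  status == 0L
}
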