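# Writes a tiny two-slice DICOM series with pydicom (an independent
# implementation of the format), with slice positions deliberately
# reversed relative to the alphabetical filename order.
write_shuffled_dicom_series <- function(dir) {
  dir.create(dir, showWarnings = FALSE)
  script <- sprintf('
import numpy as np
import pydicom
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid

def make(fname, z, base):
    fm = FileMetaDataset()
    fm.MediaStorageSOPClassUID = pydicom.uid.CTImageStorage
    fm.MediaStorageSOPInstanceUID = generate_uid()
    fm.TransferSyntaxUID = ExplicitVRLittleEndian
    ds = Dataset()
    ds.file_meta = fm
    ds.SOPClassUID = fm.MediaStorageSOPClassUID
    ds.SOPInstanceUID = fm.MediaStorageSOPInstanceUID
    ds.Rows = 6
    ds.Columns = 6
    ds.BitsAllocated = 16
    ds.BitsStored = 16
    ds.HighBit = 15
    ds.PixelRepresentation = 0
    ds.SamplesPerPixel = 1
    ds.PhotometricInterpretation = "MONOCHROME2"
    ds.PixelSpacing = [0.3, 0.3]
    ds.SliceThickness = 0.3
    ds.ImagePositionPatient = [0.0, 0.0, float(z)]
    ds.InstanceNumber = int(z / 0.3) + 1
    arr = (np.arange(36, dtype=np.uint16) + base).reshape(6, 6)
    ds.PixelData = arr.tobytes()
    ds.is_little_endian = True
    ds.is_implicit_VR = False
    ds.save_as(fname, write_like_original=False)

# alphabetical order a, b -- but a is the HIGHER slice (z = 0.3)
make("%s/a_high.dcm", 0.3, 100)
make("%s/b_low.dcm", 0.0, 0)
', dir, dir)
  res <- system2("python", c("-c", shQuote(script)), stdout = TRUE,
                 stderr = TRUE)
  if (!file.exists(file.path(dir, "a_high.dcm")))
    stop("pydicom fixture generation failed: ", paste(res, collapse = "\n"))
  invisible(dir)
}
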