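"""Bridge between SOFA (SimpleFreeFieldHRIR, netCDF-4/HDF5) files and JSON.

Usage:
  python sofa_json.py read  <file.sofa> <out.json>
  python sofa_json.py write <in.json>   <file.sofa>

The JSON object holds: fs (Hz), source_position (M x 3, [azimuth deg,
elevation deg, radius m]), ir (M x 2 x N impulse responses, receiver order
[left, right]), convention.
"""
import json
import sys

import h5py
import numpy as np


def _attr(obj, name):
    v = obj.attrs.get(name)
    if isinstance(v, bytes):
        return v.decode("utf-8", "replace")
    if isinstance(v, np.ndarray) and v.dtype.kind in "SU":
        return str(v[0])
    return v


def read(path, out):
    with h5py.File(path, "r") as f:
        conv = _attr(f, "SOFAConventions")
        if conv is None:
            raise KeyError("missing global attribute SOFAConventions")
        if str(conv) != "SimpleFreeFieldHRIR":
            raise ValueError("unsupported SOFA convention: %s" % conv)
        for name in ("Data.IR", "Data.SamplingRate", "SourcePosition"):
            if name not in f:
                raise KeyError("missing variable %s" % name)
        ir = np.asarray(f["Data.IR"], dtype=float)
        fs = float(np.ravel(f["Data.SamplingRate"])[0])
        pos = np.asarray(f["SourcePosition"], dtype=float)
    if ir.ndim != 3:
        raise ValueError("Data.IR must be 3-dimensional (M x R x N)")
    obj = {
        "convention": "SimpleFreeFieldHRIR",
        "fs": fs,
        "source_position": pos.tolist(),
        "ir": ir.tolist(),
    }
    with open(out, "w") as fh:
        json.dump(obj, fh)


def write(inp, path):
    with open(inp) as fh:
        obj = json.load(fh)
    ir = np.asarray(obj["ir"], dtype=float)
    pos = np.asarray(obj["source_position"], dtype=float)
    with h5py.File(path, "w") as f:
        f.attrs["SOFAConventions"] = np.bytes_("SimpleFreeFieldHRIR")
        f.attrs["SOFAConventionsVersion"] = np.bytes_("1.0")
        f.attrs["DataType"] = np.bytes_("FIR")
        f.create_dataset("Data.IR", data=ir)
        f.create_dataset("Data.SamplingRate", data=np.array([obj["fs"]]))
        f["Data.SamplingRate"].attrs["Units"] = np.bytes_("hertz")
        f.create_dataset("SourcePosition", data=pos)
        f["SourcePosition"].attrs["Type"] = np.bytes_("spherical")
        f["SourcePosition"].attrs["Units"] = np.bytes_(
            "degree, degree, metre")
        f.create_dataset(
            "Data.Delay", data=np.zeros((1, ir.shape[1])))


def main(argv):
    if len(argv) != 4 or argv[1] not in ("read", "write"):
        sys.stderr.write(__doc__)
        return 2
    try:
        if argv[1] == "read":
            read(argv[2], argv[3])
        else:
            write(argv[2], argv[3])
    except Exception as exc:  # surfaced to R as a format error
        sys.stderr.write("sofa_json error: %s\n" % exc)
        return 1
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
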