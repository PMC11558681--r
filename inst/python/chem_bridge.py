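"""Chemistry bridge for the screenval R package.

Called as:  python chem_bridge.py <request.json> <response.json>

The request is a JSON object {"op": ..., "smiles": [...], ...extra params}.
Supported ops:
  canonicalize  -> {"canonical": [str|null], "ok": [bool]}
  morgan        -> {"bits": [[int,...]], "ok": [bool]}   (1-based set-bit indices)
  descriptors   -> {"names": [...], "values": [[float]], "ok": [bool]}
  alerts        -> {"counts": [int], "ok": [bool]}       (needs "smarts": [...])

Descriptor list: rdkit 2024.09 descriptor registry minus Ipc/AvgIpc
(information-content indices prone to numeric overflow), fixed at 208
descriptors in registry order.
"""
import json
import math
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Descriptors

RDLogger.DisableLog("rdApp.*")

EXCLUDED_DESCRIPTORS = {"Ipc", "AvgIpc"}


def _mols(smiles):
    out = []
    for s in smiles:
        try:
            m = Chem.MolFromSmiles(s) if isinstance(s, str) else None
        except Exception:
            m = None
        out.append(m)
    return out


def op_canonicalize(req):
    mols = _mols(req["smiles"])
    canon = [Chem.MolToSmiles(m) if m is not None else None for m in mols]
    return {"canonical": canon, "ok": [m is not None for m in mols]}


def op_morgan(req):
    radius = int(req.get("radius", 2))
    n_bits = int(req.get("n_bits", 1024))
    gen = AllChem.GetMorganGenerator(radius=radius, fpSize=n_bits)
    mols = _mols(req["smiles"])
    bits, ok = [], []
    for m in mols:
        if m is None:
            bits.append([])
            ok.append(False)
        else:
            fp = gen.GetFingerprint(m)
            bits.append([b + 1 for b in fp.GetOnBits()])
            ok.append(True)
    return {"bits": bits, "ok": ok, "n_bits": n_bits}


def descriptor_functions():
    return [(n, f) for n, f in Descriptors.descList if n not in EXCLUDED_DESCRIPTORS]


def op_descriptors(req):
    funcs = descriptor_functions()
    mols = _mols(req["smiles"])
    values, ok = [], []
    for m in mols:
        if m is None:
            values.append([None] * len(funcs))
            ok.append(False)
            continue
        row = []
        for _, f in funcs:
            try:
                v = float(f(m))
                if not math.isfinite(v):
                    v = None
            except Exception:
                v = None
            row.append(v)
        values.append(row)
        ok.append(True)
    return {"names": [n for n, _ in funcs], "values": values, "ok": ok}


def op_alerts(req):
    patterns = []
    for smarts in req["smarts"]:
        p = Chem.MolFromSmarts(smarts)
        if p is None:
            raise ValueError("bad SMARTS pattern: %s" % smarts)
        patterns.append(p)
    mols = _mols(req["smiles"])
    counts, ok = [], []
    for m in mols:
        if m is None:
            counts.append(0)
            ok.append(False)
        else:
            counts.append(sum(1 for p in patterns if m.HasSubstructMatch(p)))
            ok.append(True)
    return {"counts": counts, "ok": ok}


OPS = {
    "canonicalize": op_canonicalize,
    "morgan": op_morgan,
    "descriptors": op_descriptors,
    "alerts": op_alerts,
}


def main(argv):
    with open(argv[1]) as fh:
        req = json.load(fh)
    res = OPS[req["op"]](req)
    with open(argv[2], "w") as fh:
        json.dump(res, fh)


if __name__ == "__main__":
    main(sys.argv)
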