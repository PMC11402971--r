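"""Batch Morgan/ECFP fingerprinting helper.

Reads a JSON object {"smiles": [...], "n_bits": int, "radius": int} on stdin
and writes a JSON list (one entry per input SMILES) of 0-based on-bit index
lists to stdout; an unparseable SMILES yields null at its position.
"""
import sys, json

from rdkit import Chem, RDLogger
from rdkit.Chem import rdFingerprintGenerator

RDLogger.DisableLog("rdApp.*")

req = json.load(sys.stdin)
n_bits = int(req.get("n_bits", 512))
radius = int(req.get("radius", 2))
gen = rdFingerprintGenerator.GetMorganGenerator(radius=radius, fpSize=n_bits)

out = []
for smi in req["smiles"]:
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        out.append(None)
    else:
        bv = gen.GetFingerprint(mol)
        out.append(list(bv.GetOnBits()))
json.dump(out, sys.stdout)
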