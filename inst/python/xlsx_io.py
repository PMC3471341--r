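"""Write an .xlsx workbook from a JSON build spec.

Usage: python xlsx_io.py SPEC_JSON OUT_XLSX

Spec:
{
  "sheets": [{"name": str, "hidden": bool, "rows": [[str|null, ...], ...]}],
  "validations": [{"sheet": str, "range": "A2:A7", "formula": "'_hidden'!$C$1:$C$9"}]
}
"""
import json
import sys

from openpyxl import Workbook
from openpyxl.worksheet.datavalidation import DataValidation


def main(spec_path, out_path):
    with open(spec_path) as fh:
        spec = json.load(fh)
    wb = Workbook()
    wb.remove(wb.active)
    for sh in spec["sheets"]:
        ws = wb.create_sheet(title=sh["name"])
        for row in sh["rows"]:
            ws.append([None if v is None else str(v) for v in row])
        if sh.get("hidden"):
            ws.sheet_state = "hidden"
    for dv_spec in spec.get("validations", []):
        ws = wb[dv_spec["sheet"]]
        dv = DataValidation(type="list", formula1=dv_spec["formula"],
                            allow_blank=True, showDropDown=False)
        ws.add_data_validation(dv)
        dv.add(dv_spec["range"])
    wb.save(out_path)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
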