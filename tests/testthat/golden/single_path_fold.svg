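<?xml version="1.0" encoding="UTF-8"?>
<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="1002.00" height="164.00" viewBox="0 0 1002.00 164.00">
<rect x="0" y="0" width="1002.00" height="164.00" fill="#ffffff"/>
<text x="390.00" y="22.00" text-anchor="middle" font-family="Helvetica, Arial, sans-serif" font-size="12.00" fill="#000000">a1</text>
<text x="564.00" y="22.00" text-anchor="middle" font-family="Helvetica, Arial, sans-serif" font-size="12.00" fill="#000000">a2</text>
<text x="738.00" y="22.00" text-anchor="middle" font-family="Helvetica, Arial, sans-serif" font-size="12.00" fill="#000000">a3</text>
<text x="912.00" y="22.00" text-anchor="middle" font-family="Helvetica, Arial, sans-serif" font-size="12.00" fill="#000000">a4</text>
<line x1="10.00" y1="58.00" x2="992.00" y2="58.00" stroke="#eeeeee" stroke-width="1"/>
<text x="10.00" y="51.50" font-family="Helvetica, Arial, sans-serif" font-size="12.00" fill="#000000">root process</text>
<line x1="10.00" y1="80.00" x2="992.00" y2="80.00" stroke="#eeeeee" stroke-width="1"/>
<text x="24.00" y="73.50" font-family="Helvetica, Arial, sans-serif" font-size="12.00" fill="#000000">branch B</text>
<line x1="10.00" y1="102.00" x2="992.00" y2="102.00" stroke="#eeeeee" stroke-width="1"/>
<text x="38.00" y="95.50" font-family="Helvetica, Arial, sans-serif" font-size="12.00" fill="#000000">junction D</text>
<line x1="10.00" y1="124.00" x2="992.00" y2="124.00" stroke="#eeeeee" stroke-width="1"/>
<text x="52.00" y="117.50" font-family="Helvetica, Arial, sans-serif" font-size="12.00" fill="#000000">leaf E</text>
<line x1="310.00" y1="132.00" x2="470.00" y2="132.00" stroke="#444444" stroke-width="1"/>
<line x1="310.00" y1="132.00" x2="310.00" y2="136.00" stroke="#444444" stroke-width="1"/>
<text x="310.00" y="146.00" text-anchor="middle" font-family="Helvetica, Arial, sans-serif" font-size="9.00" fill="#444444">0</text>
<line x1="390.00" y1="132.00" x2="390.00" y2="136.00" stroke="#444444" stroke-width="1"/>
<text x="390.00" y="146.00" text-anchor="middle" font-family="Helvetica, Arial, sans-serif" font-size="9.00" fill="#444444">2</text>
<line x1="470.00" y1="132.00" x2="470.00" y2="136.00" stroke="#444444" stroke-width="1"/>
<text x="470.00" y="146.00" text-anchor="middle" font-family="Helvetica, Arial, sans-serif" font-size="9.00" fill="#444444">4</text>
<text x="390.00" y="158.00" text-anchor="middle" font-family="Helvetica, Arial, sans-serif" font-size="9.00" fill="#444444">fold change</text>
<rect x="468.50" y="106.00" width="3.00" height="14.00" fill="#d62728"/>
<polygon points="438.00,108.50 433.00,117.50 443.00,117.50" fill="#2ca02c"/>
<line x1="484.00" y1="132.00" x2="644.00" y2="132.00" stroke="#444444" stroke-width="1"/>
<line x1="484.00" y1="132.00" x2="484.00" y2="136.00" stroke="#444444" stroke-width="1"/>
<text x="484.00" y="146.00" text-anchor="middle" font-family="Helvetica, Arial, sans-serif" font-size="9.00" fill="#444444">0</text>
<line x1="564.00" y1="132.00" x2="564.00" y2="136.00" stroke="#444444" stroke-width="1"/>
<text x="564.00" y="146.00" text-anchor="middle" font-family="Helvetica, Arial, sans-serif" font-size="9.00" fill="#444444">2</text>
<line x1="644.00" y1="132.00" x2="644.00" y2="136.00" stroke="#444444" stroke-width="1"/>
<text x="644.00" y="146.00" text-anchor="middle" font-family="Helvetica, Arial, sans-serif" font-size="9.00" fill="#444444">4</text>
<text x="564.00" y="158.00" text-anchor="middle" font-family="Helvetica, Arial, sans-serif" font-size="9.00" fill="#444444">fold change</text>
<rect x="522.50" y="106.00" width="3.00" height="14.00" fill="#9e9e9e"/>
<polygon points="528.00,108.50 523.00,117.50 533.00,117.50" fill="#f7b6d2"/>
<line x1="658.00" y1="132.00" x2="818.00" y2="132.00" stroke="#444444" stroke-width="1"/>
<line x1="658.00" y1="132.00" x2="658.00" y2="136.00" stroke="#444444" stroke-width="1"/>
<text x="658.00" y="146.00" text-anchor="middle" font-family="Helvetica, Arial, sans-serif" font-size="9.00" fill="#444444">0</text>
<line x1="738.00" y1="132.00" x2="738.00" y2="136.00" stroke="#444444" stroke-width="1"/>
<text x="738.00" y="146.00" text-anchor="middle" font-family="Helvetica, Arial, sans-serif" font-size="9.00" fill="#444444">2</text>
<line x1="818.00" y1="132.00" x2="818.00" y2="136.00" stroke="#444444" stroke-width="1"/>
<text x="818.00" y="146.00" text-anchor="middle" font-family="Helvetica, Arial, sans-serif" font-size="9.00" fill="#444444">4</text>
<text x="738.00" y="158.00" text-anchor="middle" font-family="Helvetica, Arial, sans-serif" font-size="9.00" fill="#444444">fold change</text>
<rect x="666.50" y="106.00" width="3.00" height="14.00" fill="#d62728"/>
<polygon points="674.00,117.50 669.00,108.50 679.00,108.50" fill="#2ca02c"/>
<line x1="832.00" y1="132.00" x2="992.00" y2="132.00" stroke="#444444" stroke-width="1"/>
<line x1="832.00" y1="132.00" x2="832.00" y2="136.00" stroke="#444444" stroke-width="1"/>
<text x="832.00" y="146.00" text-anchor="middle" font-family="Helvetica, Arial, sans-serif" font-size="9.00" fill="#444444">0</text>
<line x1="912.00" y1="132.00" x2="912.00" y2="136.00" stroke="#444444" stroke-width="1"/>
<text x="912.00" y="146.00" text-anchor="middle" font-family="Helvetica, Arial, sans-serif" font-size="9.00" fill="#444444">2</text>
<line x1="992.00" y1="132.00" x2="992.00" y2="136.00" stroke="#444444" stroke-width="1"/>
<text x="992.00" y="146.00" text-anchor="middle" font-family="Helvetica, Arial, sans-serif" font-size="9.00" fill="#444444">4</text>
<text x="912.00" y="158.00" text-anchor="middle" font-family="Helvetica, Arial, sans-serif" font-size="9.00" fill="#444444">fold change</text>
</svg>
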