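<?xml version="1.0" encoding="UTF-8"?>
<!-- Structural schema for the archive descriptor (meta.xml): an archive
     element holding one core and any number of extension file descriptors,
     each with dialect attributes, file locations, an id/coreid column and
     term-to-column field bindings.  Transcribed for offline validation of
     writer output. -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema"
           xmlns:dwc="http://rs.tdwg.org/dwc/text/"
           targetNamespace="http://rs.tdwg.org/dwc/text/"
           elementFormDefault="qualified">

  <xs:element name="archive">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="core" type="dwc:coreFileType" minOccurs="1" maxOccurs="1"/>
        <xs:element name="extension" type="dwc:extensionFileType" minOccurs="0" maxOccurs="unbounded"/>
      </xs:sequence>
      <xs:attribute name="metadata" type="xs:string" use="optional"/>
    </xs:complexType>
  </xs:element>

  <xs:complexType name="fileType">
    <xs:sequence>
      <xs:element name="location" type="xs:string" minOccurs="1" maxOccurs="unbounded"/>
    </xs:sequence>
  </xs:complexType>

  <xs:complexType name="idFieldType">
    <xs:attribute name="index" type="xs:nonNegativeInteger" use="optional"/>
  </xs:complexType>

  <xs:complexType name="fieldType">
    <xs:attribute name="index" type="xs:nonNegativeInteger" use="optional"/>
    <xs:attribute name="term" type="xs:anyURI" use="required"/>
    <xs:attribute name="default" type="xs:string" use="optional"/>
    <xs:attribute name="vocabulary" type="xs:anyURI" use="optional"/>
  </xs:complexType>

  <xs:attributeGroup name="fileAttributes">
    <xs:attribute name="rowType" type="xs:anyURI" use="required"/>
    <xs:attribute name="fieldsTerminatedBy" type="xs:string" use="optional"/>
    <xs:attribute name="linesTerminatedBy" type="xs:string" use="optional"/>
    <xs:attribute name="fieldsEnclosedBy" type="xs:string" use="optional"/>
    <xs:attribute name="encoding" type="xs:string" use="optional"/>
    <xs:attribute name="ignoreHeaderLines" type="xs:nonNegativeInteger" use="optional"/>
    <xs:attribute name="dateFormat" type="xs:string" use="optional"/>
  </xs:attributeGroup>

  <xs:complexType name="coreFileType">
    <xs:sequence>
      <xs:element name="files" type="dwc:fileType" minOccurs="1" maxOccurs="1"/>
      <xs:element name="id" type="dwc:idFieldType" minOccurs="0" maxOccurs="1"/>
      <xs:element name="field" type="dwc:fieldType" minOccurs="0" maxOccurs="unbounded"/>
    </xs:sequence>
    <xs:attributeGroup ref="dwc:fileAttributes"/>
  </xs:complexType>

  <xs:complexType name="extensionFileType">
    <xs:sequence>
      <xs:element name="files" type="dwc:fileType" minOccurs="1" maxOccurs="1"/>
      <xs:element name="coreid" type="dwc:idFieldType" minOccurs="1" maxOccurs="1"/>
      <xs:element name="field" type="dwc:fieldType" minOccurs="0" maxOccurs="unbounded"/>
    </xs:sequence>
    <xs:attributeGroup ref="dwc:fileAttributes"/>
  </xs:complexType>

</xs:schema>
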